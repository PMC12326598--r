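# Seeded generator of synthetic molecule corpora with planted
# physicochemical, in vitro and in vivo structure.
#
# Molecules are assembled from a curated fragment inventory (ring systems,
# linkers, side chains drawn from the organic subset), which guarantees
# chemical validity and scaffold diversity. In vitro task labels follow a
# logistic model on a sparse subset of fingerprint bits (so activity is a
# noisy function of substructure); in vivo task labels are coupled to the
# latent in vitro activities, emulating the statistical structure of
# preclinical liver endpoints: rare positives driven by cellular-level
# interactions.

# ring fragments written so that both the first and last atom are carbon,
# making them safely prefix- and suffix-appendable in assembled SMILES
.RING_FRAGMENTS <- c(
  "c1ccccc1",          # benzene
  "c1ccncc1",          # pyridine
  "c1cncnc1",          # pyrimidine
  "c1ccoc1",           # furan
  "c1ccsc1",           # thiophene
  "c1cc[nH]c1",        # pyrrole
  "c1nc[nH]c1",        # imidazole
  "c1ncoc1",           # oxazole
  "c1ncsc1",           # thiazole
  "c1ccc2ccccc2c1",    # naphthalene
  "c1ccc2ncccc2c1",    # quinoline
  "c1ccc2[nH]ccc2c1",  # indole
  "C1CC1",             # cyclopropane
  "C1CCC1",            # cyclobutane
  "C1CCCC1",           # cyclopentane
  "C1CCCCC1",          # cyclohexane
  "C1CCNCC1",          # piperidine
  "C1CCOCC1",          # tetrahydropyran
  "C1NCCNC1",          # piperazine
  "C1OCCNC1"           # morpholine
)

.LINKER_FRAGMENTS <- c("C", "CC", "CCC", "O", "N", "CO", "CN", "C(=O)",
                       "C=C", "S(=O)(=O)")

.PREFIX_CHAINS <- c("C", "CC", "CCC", "CC(C)", "OC", "OCC", "CCO", "NC",
                    "FC(F)(F)", "N#C", "CC(=O)N", "CS(=O)(=O)", "COC(=O)",
                    "Cl", "F", "Br")

.SUFFIX_CHAINS <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "CN", "N", "O",
                    "F", "Cl", "Br", "C(=O)O", "C(=O)N", "C(F)(F)F", "C#N",
                    "S(C)(=O)=O")

#' Specification for a synthetic corpus
#'
#' @param n_molecules corpus size (default 2000).
#' @param n_invitro number of in vitro tasks (default 20).
#' @param n_invivo number of in vivo tasks (default 5).
#' @param invitro_prevalence target positive ratio per in vitro task
#'   (scalar or vector; default 0.3, typical of a hit-enriched panel:
#'   assays selected because known toxicants hit them have far higher
#'   hit rates than random screens).
#' @param invivo_prevalence_range range the per-task in vivo prevalences
#'   are drawn from (default c(0.02, 0.2), mimicking severe liver-endpoint
#'   imbalance).
#' @param beta signal strength: the standard deviation of the structural
#'   contribution to each task's activity log-odds (the logistic noise
#'   has sd pi/sqrt(3) ~ 1.81, so the default 2.5 puts roughly two thirds
#'   of the latent variance in the planted signal).
#' @param bits_per_task number of single informative fingerprint bits per
#'   in vitro task (default 3).
#' @param pairs_per_task number of fingerprint-bit conjunctions (both
#'   substructures must co-occur) per task (default 4): binding events
#'   typically require several pharmacophoric features together, which
#'   makes activity a non-additive function of composition.
#' @param bit_pool_size size of the shared pool the per-task bits are
#'   drawn from (default 15): tasks overlap in their structural drivers,
#'   as correlated assay panels do.
#' @param noise_rate label flip rate in \[0, 0.5) (default 0.01; at low
#'   prevalence most flips create false positives, so even small rates
#'   erode the attainable precision quickly).
#' @param missing_rate fraction of in vitro entries hidden (default 0.3).
#' @param invivo_missing_rate fraction of in vivo entries hidden
#'   (default 0.1).
#' @param coupling strength of the in vitro -> in vivo coupling; at the
#'   default 1 the coupled signal carries about twice the standard
#'   deviation of the logistic noise; 0 makes in vivo labels independent
#'   of structure.
#' @param invivo_noise_sd multiplier on the logistic noise in the in vivo
#'   log-odds (default 1).
#' @param coupling_k number of in vitro activities each in vivo endpoint
#'   couples to (default 1: endpoints driven by a dominant cellular
#'   mechanism, the way transporter inhibition dominates cholestatic
#'   injury; larger values mix mechanisms).
#' @param ring2_prob probability of a second, linked ring system
#'   (default 0.5).
#' @param chain_prob probability of each terminal side chain
#'   (default 0.7).
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the spec.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_molecules = 2000L, n_invitro = 20L,
                           n_invivo = 5L, invitro_prevalence = 0.3,
                           invivo_prevalence_range = c(0.02, 0.2),
                           beta = 2.5, bits_per_task = 3L,
                           pairs_per_task = 4L, bit_pool_size = 15L,
                           noise_rate = 0.01, missing_rate = 0.3,
                           invivo_missing_rate = 0.1, coupling = 1,
                           invivo_noise_sd = 1, coupling_k = 1L,
                           ring2_prob = 0.5,
                           chain_prob = 0.7, seed = 1L) {
  stopifnot(all(invitro_prevalence > 0), all(invitro_prevalence < 1),
            noise_rate >= 0, noise_rate < 0.5,
            missing_rate >= 0, missing_rate < 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

# assemble one molecule string from the fragment inventory
.assemble_smiles <- function(spec) {
  pre <- if (stats::runif(1) < spec$chain_prob)
    sample(.PREFIX_CHAINS, 1) else ""
  ringA <- sample(.RING_FRAGMENTS, 1)
  mid <- ""
  if (stats::runif(1) < spec$ring2_prob) {
    mid <- paste0(sample(.LINKER_FRAGMENTS, 1), sample(.RING_FRAGMENTS, 1))
  }
  suf <- if (stats::runif(1) < spec$chain_prob)
    sample(.SUFFIX_CHAINS, 1) else ""
  paste0(pre, ringA, mid, suf)
}

#' Generate a synthetic molecule corpus with planted in vitro structure
#'
#' Assembles `n_molecules` unique valid molecules by seeded fragment
#' assembly, computes descriptors and fingerprints, and draws each in
#' vitro task's labels from a logistic model on a random sparse subset of
#' fingerprint bits. The intercept is calibrated on the realized sample so
#' the observed prevalence matches the target, labels are then flipped at
#' the noise rate (with the pre-flip prevalence adjusted so the expected
#' post-flip prevalence still matches), and a missingness pattern is
#' applied.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `molecules` (data.frame: molecule, smiles,
#'   scaffold_key), `descriptors` (raw descriptor matrix), `fingerprints`,
#'   `invitro` (label matrix), `latent_invitro` (pre-threshold logits, the
#'   planted ground truth), and `spec`.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(spec$seed)

  seen <- character(0)
  batch_target <- spec$n_molecules
  guard <- 0L
  while (length(seen) < spec$n_molecules) {
    guard <- guard + 1L
    if (guard > 50L) stop("fragment assembly failed to reach corpus size")
    raw <- vapply(seq_len(batch_target), function(i) .assemble_smiles(spec),
                  character(1))
    pp <- preprocess(raw)
    seen <- unique(c(seen, pp$molecules$canonical_smiles))
    batch_target <- max(100L, spec$n_molecules - length(seen))
  }
  smiles <- seen[seq_len(spec$n_molecules)]
  scaf <- murcko_scaffold(smiles)
  fp <- fingerprint_morgan(smiles)
  desc <- compute_descriptors(smiles)

  P <- spec$n_invitro
  prev <- rep_len(spec$invitro_prevalence, P)
  N <- spec$n_molecules
  latent <- matrix(0, N, P)
  labels <- matrix(NA_real_, N, P)
  bit_prev <- colMeans(fp)
  informative_pool <- which(bit_prev >= 0.05 & bit_prev <= 0.6)
  if (length(informative_pool) < spec$bits_per_task) {
    stop("too few informative fingerprint bits; corpus not diverse enough")
  }
  shared_pool <- sample(informative_pool,
                        min(spec$bit_pool_size, length(informative_pool)))
  for (p in seq_len(P)) {
    # resample until the bit combination actually varies over the corpus
    for (try in 1:20) {
      bits <- sample(shared_pool, min(spec$bits_per_task,
                                      length(shared_pool)))
      w <- sample(c(-1, 1), length(bits), replace = TRUE) *
        stats::runif(length(bits), 0.5, 1.5)
      eta <- as.vector(fp[, bits, drop = FALSE] %*% w)
      # conjunction terms: both substructures must be present
      for (k in seq_len(spec$pairs_per_task)) {
        pr <- sample(shared_pool, 2)
        wk <- sample(c(-1, 1), 1) * stats::runif(1, 1, 2)
        eta <- eta + wk * (fp[, pr[1]] * fp[, pr[2]])
      }
      if (stats::sd(eta) > 0) break
    }
    if (stats::sd(eta) == 0) stop("degenerate fingerprint bits for task")
    # standardize so beta is the log-odds sd of the structural signal
    eta <- spec$beta * as.vector(scale(eta))
    z <- eta + stats::rlogis(N)
    latent[, p] <- eta
    # pre-flip prevalence adjusted so flips leave the target intact
    p0 <- (prev[p] - spec$noise_rate) / (1 - 2 * spec$noise_rate)
    if (p0 <= 0 || p0 >= 1) {
      stop(sprintf("prevalence %g unreachable at noise rate %g",
                   prev[p], spec$noise_rate))
    }
    y <- numeric(N)
    y[order(z, decreasing = TRUE)[seq_len(round(p0 * N))]] <- 1
    # count-exact, label-stratified flips and missingness keep the
    # observed prevalence on target (up to rounding) at every seed
    nf <- round(spec$noise_rate * N)
    if (nf > 0) {
      nf_pos <- min(round(nf * p0), sum(y == 1))
      fl <- c(sample(which(y == 1), nf_pos),
              sample(which(y == 0), nf - nf_pos))
      y[fl] <- 1 - y[fl]
    }
    nm <- round(spec$missing_rate * N)
    if (nm > 0) {
      nm_pos <- min(round(nm * mean(y == 1)), sum(y == 1) - 1L)
      ms <- c(sample(which(y == 1), nm_pos),
              sample(which(y == 0), nm - nm_pos))
      y[ms] <- NA_real_
    }
    labels[, p] <- y
  }
  ids <- sprintf("M%05d", seq_len(N))
  colnames(labels) <- sprintf("assay%02d", seq_len(P))
  rownames(labels) <- ids
  rownames(fp) <- ids
  rownames(desc) <- ids
  list(
    molecules = data.frame(molecule = ids, smiles = smiles,
                           scaffold_key = scaf, stringsAsFactors = FALSE),
    descriptors = desc,
    fingerprints = fp,
    invitro = label_matrix(labels),
    latent_invitro = latent,
    spec = spec
  )
}

#' Generate coupled in vivo endpoints and raw study tables
#'
#' Each in vivo task's log-odds is a coupling-weighted sum of the
#' molecule's standardized latent in vitro activities plus noise,
#' thresholded to a small prevalence. Also emits a dose/time biochemistry
#' readout table and an ordinal severity table whose pooled binarization
#' reproduces the generated labels exactly.
#'
#' @param corpus result of [generate_corpus()].
#' @param spec the same [synthetic_spec()] (or one with a different
#'   `coupling`).
#' @return list with `invivo` (label matrix), `readouts` (an
#'   [endpoint_study()] of continuous dose/time values with thresholds),
#'   `severities` (an [endpoint_study()] of ordinal grades), and
#'   `prevalence` (per-task targets).
#' @export
generate_invivo_study <- function(corpus, spec = corpus$spec) {
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(spec$seed + 7919L)

  N <- nrow(corpus$latent_invitro)
  Pvit <- ncol(corpus$latent_invitro)
  Pv <- spec$n_invivo
  lat <- scale(corpus$latent_invitro)
  prev <- stats::runif(Pv, spec$invivo_prevalence_range[1],
                       spec$invivo_prevalence_range[2])
  labels <- matrix(NA_real_, N, Pv)
  for (p in seq_len(Pv)) {
    src <- sample(Pvit, min(spec$coupling_k, Pvit))
    w <- stats::runif(length(src), 0.5, 1.5)
    eta <- as.vector(lat[, src, drop = FALSE] %*% w)
    if (stats::sd(eta) > 0) eta <- eta / stats::sd(eta)
    z <- 2 * spec$coupling * eta +
      spec$invivo_noise_sd * stats::rlogis(N)
    y <- numeric(N)
    y[order(z, decreasing = TRUE)[seq_len(round(prev[p] * N))]] <- 1
    nm <- round(spec$invivo_missing_rate * N)
    if (nm > 0) {
      nm_pos <- min(round(nm * mean(y == 1)), sum(y == 1) - 1L)
      ms <- c(sample(which(y == 1), nm_pos),
              sample(which(y == 0), nm - nm_pos))
      y[ms] <- NA_real_
    }
    labels[, p] <- y
  }
  endpoints <- c("ALT", "AST", "ALP", "GTP", "TC", "TG", "TBIL", "DBIL")
  epnames <- if (Pv <= length(endpoints)) endpoints[seq_len(Pv)] else
    c(endpoints, sprintf("EP%02d", seq_len(Pv - length(endpoints))))
  colnames(labels) <- epnames
  rownames(labels) <- corpus$molecules$molecule
  th <- rep(2, Pv)
  names(th) <- epnames

  doses <- c(1, 2, 3)
  times <- c(4, 8, 15, 29)
  grid <- expand.grid(dose = doses, time = times)
  rec <- vector("list", N * Pv)
  sev <- vector("list", N * Pv)
  k <- 0L
  for (p in seq_len(Pv)) {
    for (i in seq_len(N)) {
      if (is.na(labels[i, p])) next
      k <- k + 1L
      vals <- th[p] * stats::runif(nrow(grid), 0.3, 0.95)
      grade <- rep(0, nrow(grid))
      if (labels[i, p] == 1) {
        hit <- sample.int(nrow(grid), 1)
        vals[hit] <- th[p] * stats::runif(1, 1.2, 2.5)
        grade[hit] <- sample(1:5, 1)
      }
      rec[[k]] <- data.frame(
        molecule = corpus$molecules$molecule[i], endpoint = epnames[p],
        dose = grid$dose, time = grid$time, value = vals,
        stringsAsFactors = FALSE)
      sev[[k]] <- data.frame(
        molecule = corpus$molecules$molecule[i], endpoint = epnames[p],
        dose = grid$dose, time = grid$time, value = grade,
        stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rec[seq_len(k)])
  sev <- do.call(rbind, sev[seq_len(k)])
  list(invivo = label_matrix(labels),
       readouts = endpoint_study(rec, thresholds = th),
       severities = endpoint_study(sev),
       prevalence = prev)
}

#' Write the full fixture bundle to a directory
#'
#' Emits corpus CSV, in vitro and in vivo label CSVs, the long-format
#' readout CSV and the spec as YAML. Byte-identical output for a given
#' spec (same seed).
#'
#' @param corpus from [generate_corpus()].
#' @param study from [generate_invivo_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_fixture_bundle <- function(corpus, study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("corpus.csv", "invitro.csv", "invivo.csv",
                            "readouts.csv", "spec.yaml"))
  utils::write.csv(corpus$molecules, paths[1], row.names = FALSE)
  write_label_csv(corpus$invitro, paths[2])
  write_label_csv(study$invivo, paths[3])
  utils::write.csv(study$readouts$records, paths[4], row.names = FALSE)
  sp <- corpus$spec
  yaml::write_yaml(lapply(unclass(sp), function(x) unname(x)), paths[5])
  invisible(paths)
}
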
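# SMILES token pattern: bracket atoms, two-letter halogens, aromatic organics,
# ring-bond digits (incl. %nn), bonds, branches, dot.
.SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]*\\]|Br|Cl|",
  "[BCNOPSFI]|[bcnops]|",
  "%[0-9]{2}|[0-9]|",
  "[=#:/\\\\\\+\\-\\(\\)\\.\\*~@]"
)

.ORGANIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I", "H")

.SPECIAL_TOKENS <- c("[PAD]", "[BEGIN]", "[END]", "[MASK]", "[UNK]")

#' Tokenize SMILES strings
#'
#' Splits each SMILES string into chemically meaningful tokens: bracket
#' atoms as single tokens, two-letter elements (Cl, Br), aromatic atoms,
#' ring-closure digits and bond symbols. Characters not matched by the
#' token grammar are kept as single-character tokens (they map to the
#' unknown token at encoding time).
#'
#' @param smiles character vector of SMILES strings.
#' @return A list of character vectors, one per input string.
#' @export
#' @examples
#' smiles_tokenize("CC(=O)Oc1ccccc1C(=O)O")
smiles_tokenize <- function(smiles) {
  stopifnot(is.character(smiles))
  lapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) stop("cannot tokenize an empty SMILES string")
    m <- gregexpr(.SMILES_TOKEN_RE, s, perl = TRUE)[[1]]
    toks <- regmatches(s, list(m))[[1]]
    if (sum(nchar(toks)) != nchar(s)) {
      # splice unmatched characters back in, in order, as 1-char tokens
      covered <- rep(FALSE, nchar(s))
      for (i in seq_along(toks)) {
        covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
      }
      pieces <- character(0)
      pos <- 1L
      ti <- 1L
      while (pos <= nchar(s)) {
        if (covered[pos]) {
          pieces <- c(pieces, toks[ti])
          pos <- pos + nchar(toks[ti])
          ti <- ti + 1L
        } else {
          pieces <- c(pieces, substr(s, pos, pos))
          pos <- pos + 1L
        }
      }
      toks <- pieces
    }
    toks
  })
}

# element symbols appearing in a token vector (from organic-subset tokens and
# bracket atoms); used for the metal filter
.token_elements <- function(tokens) {
  els <- character(0)
  for (tk in tokens) {
    if (tk %in% c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")) {
      els <- c(els, tk)
    } else if (tk %in% c("b", "c", "n", "o", "p", "s")) {
      els <- c(els, toupper(tk))
    } else if (startsWith(tk, "[")) {
      m <- regmatches(tk, regexec("^\\[[0-9]*([A-Za-z][a-z]?)", tk))[[1]]
      if (length(m) == 2L) {
        el <- m[2]
        # aromatic lowercase single letter inside brackets, e.g. [nH]
        if (el %in% c("b", "c", "n", "o", "p", "s")) el <- toupper(el)
        if (nchar(el) == 2L && substr(el, 2, 2) == "H" &&
            toupper(substr(el, 1, 1)) %in% c("B", "C", "N", "O", "P", "S")) {
          el <- toupper(substr(el, 1, 1)) # e.g. [nH], [NH2+]
        }
        els <- c(els, el)
      }
    }
  }
  unique(els)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical (aromatic) form in one batch
#' call. Unparseable inputs yield `NA`.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
smiles_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  res <- .obabel_convert(smiles[ok], "-ocan")
  out[ok] <- res
  out
}

# run obabel over a batch of SMILES keeping input order via index titles;
# returns NA for entries obabel could not parse
.obabel_convert <- function(smiles, ofmt, extra = character(0)) {
  fin <- tempfile(fileext = ".smi")
  on.exit(unlink(fin), add = TRUE)
  writeLines(paste(smiles, paste0("i", seq_along(smiles))), fin)
  lines <- suppressWarnings(
    system2("obabel", c(fin, ofmt, "-e", extra), stdout = TRUE, stderr = FALSE)
  )
  out <- rep(NA_character_, length(smiles))
  if (length(lines) == 0L) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2L) {
      idx <- suppressWarnings(as.integer(sub("^i", "", trimws(p[length(p)]))))
      if (!is.na(idx)) out[idx] <- trimws(p[1])
    }
  }
  out
}

#' Preprocess a list of SMILES strings
#'
#' Applies the standard ingestion filters: the SMILES must parse, must be a
#' single fragment (no salts / counter-ions), must contain only organic-subset
#' elements (B, C, N, O, P, S, F, Cl, Br, I, H -- anything else is treated as
#' a metal or exotic element), and its canonical form must not exceed
#' `max_length` characters. Kept molecules are canonicalized and annotated
#' with their Bemis-Murcko scaffold.
#'
#' @param smiles character vector of raw SMILES.
#' @param max_length maximum canonical SMILES length (default 128).
#' @return A list with `molecules` (data.frame: `raw_smiles`,
#'   `canonical_smiles`, `scaffold_key`) and `rejected` (data.frame:
#'   `smiles`, `reason`). `scaffold_key` is the canonical SMILES of the
#'   Bemis-Murcko framework, `""` for acyclic molecules.
#' @export
preprocess <- function(smiles, max_length = 128L) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  reason <- rep(NA_character_, n)
  canon <- rep(NA_character_, n)

  empty <- is.na(smiles) | !nzchar(smiles)
  reason[empty] <- "empty"

  todo <- which(!empty)
  if (length(todo)) {
    canon[todo] <- smiles_canonicalize(smiles[todo])
    bad <- todo[is.na(canon[todo])]
    reason[bad] <- "unparseable"
  }

  alive <- which(is.na(reason))
  if (length(alive)) {
    multi <- alive[grepl(".", canon[alive], fixed = TRUE)]
    reason[multi] <- "multi-fragment (salt)"
  }
  alive <- which(is.na(reason))
  if (length(alive)) {
    toks <- smiles_tokenize(canon[alive])
    offenders <- vapply(toks, function(tk) {
      els <- .token_elements(tk)
      any(!els %in% .ORGANIC_ELEMENTS)
    }, logical(1))
    reason[alive[offenders]] <- "non-organic element (metal)"
  }
  alive <- which(is.na(reason))
  if (length(alive)) {
    long <- alive[nchar(canon[alive]) > max_length]
    reason[long] <- sprintf("length > %d", max_length)
  }

  keep <- which(is.na(reason))
  scaf <- character(length(keep))
  if (length(keep)) scaf <- murcko_scaffold(canon[keep])
  list(
    molecules = data.frame(
      raw_smiles = smiles[keep],
      canonical_smiles = canon[keep],
      scaffold_key = scaf,
      stringsAsFactors = FALSE
    ),
    rejected = data.frame(
      smiles = smiles[!is.na(reason)],
      reason = reason[!is.na(reason)],
      stringsAsFactors = FALSE
    )
  )
}

#' Bemis-Murcko scaffold
#'
#' Computes the Bemis-Murcko framework (ring systems plus the linkers
#' connecting them, retaining atoms multiply bonded to the framework, e.g.
#' exocyclic carbonyl oxygens) and returns its canonical SMILES. Acyclic
#' molecules return `""`.
#'
#' @param smiles character vector of valid (parseable) SMILES.
#' @return character vector of scaffold canonical SMILES.
#' @export
murcko_scaffold <- function(smiles) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (n == 0L) return(character(0))
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                       paste(smiles, collapse = "\n"))
  recs <- strsplit(sdf_txt, "\\$\\$\\$\\$\n")[[1]]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) != n) {
    stop("murcko_scaffold: SMILES batch contained unparseable entries")
  }
  out <- rep("", n)
  sub_sdf <- character(n)
  has_ring <- logical(n)
  for (i in seq_len(n)) {
    g <- .parse_v2000(recs[i])
    core <- .murcko_core(g)
    if (length(core)) {
      has_ring[i] <- TRUE
      sub_sdf[i] <- .write_v2000(g, core, title = paste0("i", i))
    }
  }
  idx <- which(has_ring)
  if (length(idx)) {
    cans <- ChemmineOB::convertFormat("SDF", "CAN",
                                      paste(sub_sdf[idx], collapse = ""))
    lines <- strsplit(cans, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    for (p in parts) {
      j <- suppressWarnings(as.integer(sub("^i", "", trimws(p[length(p)]))))
      if (!is.na(j)) out[j] <- trimws(p[1])
    }
  }
  out
}

# minimal V2000 record reader: atoms (element, charge) and bonds (a1,a2,order)
.parse_v2000 <- function(rec) {
  ln <- strsplit(rec, "\n", fixed = TRUE)[[1]]
  counts <- ln[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atoms <- character(na)
  for (i in seq_len(na)) {
    atoms[i] <- trimws(substr(ln[4 + i], 32, 34))
  }
  bonds <- matrix(0L, nrow = nb, ncol = 3)
  for (i in seq_len(nb)) {
    l <- ln[4 + na + i]
    bonds[i, ] <- c(as.integer(substr(l, 1, 3)),
                    as.integer(substr(l, 4, 6)),
                    as.integer(substr(l, 7, 9)))
  }
  chg <- integer(na)
  for (l in grep("^M  CHG", ln, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) {
      chg[f[2 * j]] <- f[2 * j + 1]
    }
  }
  list(atoms = atoms, bonds = bonds, charge = chg)
}

# Murcko framework atom set: the 2-core of the molecular graph (iteratively
# strip degree<=1 atoms, which removes all acyclic appendages and leaves rings
# plus inter-ring linkers), then restore atoms attached to the core by bonds
# of order >= 2
.murcko_core <- function(g) {
  na <- length(g$atoms)
  if (na == 0L) return(integer(0))
  alive <- rep(TRUE, na)
  deg <- function() {
    d <- integer(na)
    if (nrow(g$bonds)) {
      for (i in seq_len(nrow(g$bonds))) {
        a <- g$bonds[i, 1]; b <- g$bonds[i, 2]
        if (alive[a] && alive[b]) {
          d[a] <- d[a] + 1L
          d[b] <- d[b] + 1L
        }
      }
    }
    d
  }
  repeat {
    d <- deg()
    drop <- alive & d <= 1L
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  core <- which(alive)
  if (!length(core)) return(integer(0))
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      a <- g$bonds[i, 1]; b <- g$bonds[i, 2]; o <- g$bonds[i, 3]
      if (o >= 2L) {
        if (alive[a] && !alive[b]) core <- c(core, b)
        if (alive[b] && !alive[a]) core <- c(core, a)
      }
    }
  }
  sort(unique(core))
}

# write the induced subgraph on `keep` as a V2000 record (zero coordinates;
# OpenBabel re-perceives aromaticity when canonicalizing)
.write_v2000 <- function(g, keep, title = "") {
  idx <- integer(length(g$atoms))
  idx[keep] <- seq_along(keep)
  bsel <- g$bonds[g$bonds[, 1] %in% keep & g$bonds[, 2] %in% keep, ,
                  drop = FALSE]
  hdr <- paste0(title, "\n vitroembed scaffold\n\n",
                sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n",
                        length(keep), nrow(bsel)))
  at <- vapply(keep, function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0\n",
            0, 0, 0, g$atoms[i])
  }, character(1))
  bd <- character(nrow(bsel))
  if (nrow(bsel)) {
    bd <- vapply(seq_len(nrow(bsel)), function(i) {
      sprintf("%3d%3d%3d  0  0  0  0\n",
              idx[bsel[i, 1]], idx[bsel[i, 2]], bsel[i, 3])
    }, character(1))
  }
  chg <- ""
  chgat <- keep[g$charge[keep] != 0L]
  if (length(chgat)) {
    chg <- paste0(vapply(chgat, function(i) {
      sprintf("M  CHG  1 %3d %3d\n", idx[i], g$charge[i])
    }, character(1)), collapse = "")
  }
  paste0(hdr, paste0(at, collapse = ""), paste0(bd, collapse = ""),
         chg, "M  END\n$$$$\n")
}

#' Circular (ECFP) fingerprints
#'
#' Computes extended-connectivity fingerprints, hashed to a fixed-length
#' binary vector, for a batch of molecules. Default is ECFP with diameter 6
#' (radius 3) folded to 1024 bits. Deterministic for a given canonical
#' SMILES and invariant to the input atom ordering.
#'
#' @param smiles character vector of valid SMILES.
#' @param nbits fingerprint length (default 1024).
#' @param diameter circular diameter (0, 2, 4, 6, 8 or 10; default 6).
#' @return binary integer matrix, `length(smiles)` x `nbits`.
#' @export
fingerprint_morgan <- function(smiles, nbits = 1024L, diameter = 6L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (!diameter %in% c(0L, 2L, 4L, 6L, 8L, 10L)) {
    stop("diameter must be one of 0, 2, 4, 6, 8, 10")
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".fps")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(smiles, paste0("i", seq_along(smiles))), fin)
  suppressWarnings(system2(
    "obabel",
    c(fin, "-ofps", "-xf", paste0("ECFP", diameter), "-xN", nbits,
      "-e", "-O", fout),
    stdout = FALSE, stderr = FALSE
  ))
  lines <- readLines(fout)
  lines <- lines[!startsWith(lines, "#")]
  fp <- matrix(0L, nrow = length(smiles), ncol = nbits)
  hexmap <- .hex_bit_table()
  parts <- strsplit(lines, "\t", fixed = TRUE)
  seen <- rep(FALSE, length(smiles))
  for (p in parts) {
    if (length(p) < 2L) next
    j <- suppressWarnings(as.integer(sub("^i", "", trimws(p[2]))))
    if (is.na(j)) next
    hx <- strsplit(tolower(p[1]), "")[[1]]
    fp[j, ] <- as.integer(unlist(hexmap[hx], use.names = FALSE))
    seen[j] <- TRUE
  }
  if (!all(seen)) {
    stop("fingerprint_morgan: unparseable SMILES at positions ",
         paste(which(!seen), collapse = ", "))
  }
  fp
}

.hex_bit_table <- function() {
  tbl <- lapply(0:15, function(v) {
    as.integer(rev(as.integer(intToBits(v)[1:4])))
  })
  names(tbl) <- c(0:9, letters[1:6])
  tbl
}

#' Physicochemical descriptors
#'
#' Computes a fixed inventory of continuous molecular descriptors:
#' OpenBabel properties (molecular weight, logP, topological polar surface
#' area, molar refractivity, hydrogen-bond acceptor/donor counts, fluorine
#' count) plus structural counts derived from the canonical SMILES (per-
#' element heavy-atom counts, aromatic atoms, ring closures, branches,
#' double/triple bonds, heavy atom total, string length).
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric matrix, one row per molecule, named descriptor columns.
#' @export
compute_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ob <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                               identity)
  pr <- ChemmineOB::prop_OB(ob)
  if (nrow(pr) != length(smiles)) {
    stop("compute_descriptors: unparseable SMILES in batch")
  }
  num <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
  base <- as.matrix(pr[, num, drop = FALSE])
  storage.mode(base) <- "double"

  toks <- smiles_tokenize(smiles)
  cnt <- function(f) vapply(toks, f, numeric(1))
  el_count <- function(sym, arom) {
    cnt(function(tk) {
      sum(tk %in% c(sym, arom)) +
        sum(grepl(paste0("^\\[[0-9]*", sym, "(?![a-z])"), tk, perl = TRUE)) +
        sum(grepl(paste0("^\\[", arom, "(?![a-z])"), tk, perl = TRUE))
    })
  }
  extra <- cbind(
    nC  = el_count("C", "c"),
    nN  = el_count("N", "n"),
    nO  = el_count("O", "o"),
    nS  = el_count("S", "s"),
    nP  = el_count("P", "p"),
    nCl = cnt(function(tk) sum(tk == "Cl")),
    nBr = cnt(function(tk) sum(tk == "Br")),
    nI  = cnt(function(tk) sum(tk == "I")),
    n_aromatic = cnt(function(tk) {
      sum(tk %in% c("b", "c", "n", "o", "p", "s")) +
        sum(grepl("^\\[[bcnops]", tk))
    }),
    n_ring_closure = cnt(function(tk) {
      sum(grepl("^[0-9]$|^%[0-9]{2}$", tk)) / 2
    }),
    n_branch = cnt(function(tk) sum(tk == "(")),
    n_double = cnt(function(tk) sum(tk == "=")),
    n_triple = cnt(function(tk) sum(tk == "#")),
    n_heavy = cnt(function(tk) {
      sum(tk %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                    "b", "c", "n", "o", "p", "s")) +
        sum(startsWith(tk, "["))
    }),
    smiles_length = nchar(smiles)
  )
  m <- cbind(base, extra)
  rownames(m) <- NULL
  m
}

#' Normalize descriptors on a training subset
#'
#' Z-scores each descriptor column using mean and standard deviation fitted
#' on `fit_idx` rows only (the training molecules). Columns with zero
#' variance on the fit subset are dropped and reported.
#'
#' @param x numeric descriptor matrix.
#' @param fit_idx integer indices of the rows used to fit the statistics.
#' @return list with `values` (normalized matrix), `center`, `scale`
#'   (named vectors over kept columns), and `dropped` (names of
#'   zero-variance columns).
#' @export
normalize_descriptors <- function(x, fit_idx = seq_len(nrow(x))) {
  stopifnot(is.matrix(x), length(fit_idx) >= 1L)
  mu <- colMeans(x[fit_idx, , drop = FALSE])
  sd <- apply(x[fit_idx, , drop = FALSE], 2, stats::sd)
  keep <- which(sd > 0 & is.finite(sd))
  if (!length(keep)) stop("all descriptors are constant on the fit subset")
  vals <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sd[keep], "/")
  list(values = vals, center = mu[keep], scale = sd[keep],
       dropped = setdiff(colnames(x), colnames(x)[keep]))
}

#' Build a token vocabulary from a SMILES corpus
#'
#' @param smiles character vector (typically the training corpus).
#' @return character vector of tokens; positions 1-5 are the special tokens
#'   `[PAD]`, `[BEGIN]`, `[END]`, `[MASK]`, `[UNK]`, followed by the sorted
#'   corpus tokens.
#' @export
build_vocab <- function(smiles) {
  # radix sort: byte order, independent of the session's collation locale,
  # so a vocabulary (and everything trained on it) is reproducible anywhere
  toks <- sort(unique(unlist(smiles_tokenize(smiles))), method = "radix")
  c(.SPECIAL_TOKENS, setdiff(toks, .SPECIAL_TOKENS))
}

#' Encode a SMILES string to token indices
#'
#' Wraps the token sequence in begin/end markers and maps tokens absent
#' from the vocabulary to the unknown token. Indices are 1-based into
#' `vocab`.
#'
#' @param smiles character vector.
#' @param vocab vocabulary from [build_vocab()].
#' @param max_length maximum sequence length including the begin/end
#'   markers (default 128); longer sequences raise an error.
#' @return list of integer vectors.
#' @export
encode_smiles <- function(smiles, vocab, max_length = 128L) {
  toks <- smiles_tokenize(smiles)
  lapply(toks, function(tk) {
    ids <- match(tk, vocab)
    ids[is.na(ids)] <- match("[UNK]", vocab)
    ids <- c(match("[BEGIN]", vocab), ids, match("[END]", vocab))
    if (length(ids) > max_length) {
      stop(sprintf("token sequence length %d exceeds max_length %d",
                   length(ids), max_length))
    }
    as.integer(ids)
  })
}

#' Decode token indices back to a SMILES string
#'
#' Drops special tokens; the round trip `decode(encode(s))` reproduces the
#' input for any string whose tokens are all in the vocabulary.
#'
#' @param ids integer vector or list of integer vectors.
#' @param vocab vocabulary.
#' @return character vector.
#' @export
decode_smiles <- function(ids, vocab) {
  if (!is.list(ids)) ids <- list(ids)
  vapply(ids, function(v) {
    tk <- vocab[v]
    paste(tk[!tk %in% .SPECIAL_TOKENS], collapse = "")
  }, character(1))
}

#' Scaffold-disjoint K-fold split
#'
#' Groups molecules by Bemis-Murcko scaffold (each acyclic molecule, with
#' empty scaffold key, forms its own group) and assigns whole groups to
#' folds by greedy bin packing: groups are taken largest first (ties broken
#' by a seeded random order) and placed into the currently smallest fold,
#' producing scaffold-disjoint folds of near-equal size. The designated
#' test fold is the one containing the most distinct scaffold groups, ties
#' broken by the lowest fold id.
#'
#' @param scaffold_keys character vector of scaffold keys, one per molecule.
#' @param K number of folds (default 5).
#' @param seed integer seed for tie-breaking.
#' @return list with `fold_id` (integer vector in 1..K) and `test_fold`.
#' @export
scaffold_split <- function(scaffold_keys, K = 5L, seed = 1L) {
  stopifnot(is.character(scaffold_keys))
  if (K < 2L) stop("K must be >= 2")
  n <- length(scaffold_keys)
  key <- ifelse(scaffold_keys == "" | is.na(scaffold_keys),
                paste0(".acyclic", seq_len(n)), scaffold_keys)
  # radix-ordered levels keep the grouping (and greedy packing) identical
  # across collation locales
  groups <- split(seq_len(n),
                  factor(key, levels = sort(unique(key), method = "radix")))
  if (length(groups) < K) {
    stop(sprintf("only %d scaffold groups for K=%d folds", length(groups), K))
  }
  sizes <- lengths(groups)
  old <- .rng_snapshot()
  on.exit(.rng_restore(old), add = TRUE)
  set.seed(seed)
  ord <- order(-sizes, sample.int(length(groups)))
  fold_of_group <- integer(length(groups))
  fold_sizes <- integer(K)
  group_counts <- integer(K)
  for (g in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[g] <- f
    fold_sizes[f] <- fold_sizes[f] + sizes[g]
    group_counts[f] <- group_counts[f] + 1L
  }
  fold_id <- integer(n)
  for (g in seq_along(groups)) fold_id[groups[[g]]] <- fold_of_group[g]
  list(fold_id = fold_id, test_fold = which.max(group_counts))
}

# save/restore the global RNG state so seeded helpers don't disturb callers
.rng_snapshot <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
}

.rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  } else {
    assign(".Random.seed", old, envir = .GlobalEnv)
  }
}

#' Read SMILES from a CSV or .smi file
#'
#' CSV files must have a header with a `smiles` column; `.smi` files are
#' one SMILES per line with an optional whitespace-separated name.
#'
#' @param path file path.
#' @return character vector of SMILES.
#' @export
read_smiles <- function(path) {
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln))]
    vapply(strsplit(trimws(ln), "\\s+"), `[[`, character(1), 1L)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV must contain a `smiles` column")
    as.character(df$smiles)
  }
}

#' Write vocabulary to a plain-text file (one token per line)
#' @param vocab character vector.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) writeLines(vocab, path)

#' Read vocabulary from a plain-text file
#' @param path file path.
#' @return character vector.
#' @export
read_vocab <- function(path) readLines(path)
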
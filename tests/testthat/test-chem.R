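test_that("preprocess keeps clean molecules and logs rejections", {
  res <- preprocess(c(
    "CC(=O)OC1=CC=CC=C1C(=O)O",   # aspirin, kekulized input
    "[Na+].CC(=O)[O-]",           # salt
    "C1CC",                       # unparseable
    "CC[Fe]CC",                   # metal
    strrep("C", 150),             # too long
    "CCO"
  ))
  expect_equal(nrow(res$molecules), 2L)
  expect_equal(res$molecules$canonical_smiles[1], "CC(=O)Oc1ccccc1C(=O)O")
  expect_setequal(res$rejected$reason,
                  c("multi-fragment (salt)", "unparseable",
                    "non-organic element (metal)", "length > 128"))
})

test_that("canonicalization is idempotent and resolves equivalent SMILES", {
  variants <- list(
    aspirin = c("CC(=O)OC1=CC=CC=C1C(=O)O", "O=C(O)c1ccccc1OC(C)=O"),
    ethanol = c("CCO", "OCC", "C(O)C"),
    pyridine = c("c1ccncc1", "C1=CC=NC=C1")
  )
  for (v in variants) {
    canon <- smiles_canonicalize(v)
    expect_length(unique(canon), 1L)
    expect_equal(smiles_canonicalize(canon), canon)
    expect_length(unique(murcko_scaffold(canon)), 1L)
  }
  corpus <- small_corpus()
  canon <- corpus$molecules$smiles
  expect_equal(smiles_canonicalize(canon), canon)
})

test_that("Murcko scaffolds keep frameworks and drop side chains", {
  expect_equal(murcko_scaffold("CCO"), "")                    # acyclic
  expect_equal(murcko_scaffold("CC(=O)Oc1ccccc1C(=O)O"), "c1ccccc1")
  # exocyclic carbonyl is part of the framework
  expect_equal(murcko_scaffold("O=C1CCCCC1"), "O=C1CCCCC1")
  # an acyl side chain is removed entirely, carbonyl included
  expect_equal(murcko_scaffold("CC(=O)CCc1ccccc1"), "c1ccccc1")
  # linkers between rings are retained
  scaf <- murcko_scaffold("c1ccccc1CCc1ccncc1")
  expect_true(grepl("CC", scaf))
  # two molecules sharing a core share a scaffold key
  expect_length(unique(murcko_scaffold(
    c("Cc1ccccc1", "CCOc1ccccc1", "c1ccccc1"))), 1L)
})

test_that("fingerprints are 1024-bit, deterministic and order-invariant", {
  fp <- fingerprint_morgan(c("CC(=O)Oc1ccccc1C(=O)O", "C", "OCC", "CCO"))
  expect_equal(ncol(fp), 1024L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gt(sum(fp[1, ]), 0)
  expect_lt(sum(fp[2, ]), sum(fp[1, ]))          # methane has fewer bits
  expect_equal(fp[3, ], fp[4, ])                 # OCC == CCO
  # invariance across input atom orderings of the same molecule
  fpa <- fingerprint_morgan(c("CC(=O)OC1=CC=CC=C1C(=O)O",
                              "O=C(O)c1ccccc1OC(C)=O"))
  expect_equal(fpa[1, ], fpa[2, ])
})

test_that("descriptors are finite, monotone in size, and z-scorable", {
  d <- compute_descriptors(c("C", "CC(=O)Oc1ccccc1C(=O)O", "CCO"))
  expect_true(all(is.finite(d)))
  expect_lt(d[1, "MW"], d[2, "MW"])
  nd <- normalize_descriptors(d)
  expect_true(all(abs(colMeans(nd$values)) < 1e-8))
  expect_true(all(abs(apply(nd$values, 2, sd) - 1) < 1e-8))
  # zero-variance columns on the fit subset are dropped and reported
  d2 <- cbind(d, const = 1)
  nd2 <- normalize_descriptors(d2)
  expect_true("const" %in% nd2$dropped)
  expect_error(normalize_descriptors(matrix(1, 3, 2)), "constant")
})

test_that("tokenizer produces chemistry-aware tokens that round-trip", {
  expect_equal(smiles_tokenize("CCO")[[1]], c("C", "C", "O"))
  expect_equal(smiles_tokenize("CC[NH3+]Cl")[[1]],
               c("C", "C", "[NH3+]", "Cl"))
  expect_equal(smiles_tokenize("C1=CC=CC=C1")[[1]],
               c("C", "1", "=", "C", "C", "=", "C", "C", "=", "C", "1"))
  corpus <- small_corpus()
  vocab <- build_vocab(corpus$molecules$smiles)
  ids <- encode_smiles(corpus$molecules$smiles, vocab)
  expect_true(all(unlist(ids) <= length(vocab)))
  expect_equal(decode_smiles(ids, vocab), corpus$molecules$smiles)
  # encoding wraps in begin/end; unknown symbols map to [UNK]
  enc <- encode_smiles("CCO", vocab)[[1]]
  expect_equal(vocab[enc[1]], "[BEGIN]")
  expect_equal(vocab[enc[length(enc)]], "[END]")
  enc_unk <- encode_smiles("[Se]", c("[PAD]", "[BEGIN]", "[END]", "[MASK]",
                                     "[UNK]", "C"))[[1]]
  expect_equal(enc_unk[2], 5L)
  expect_error(encode_smiles("", vocab), "empty")
  expect_error(encode_smiles(strrep("C", 130), vocab, max_length = 128L),
               "max_length")
})

test_that("scaffold split is scaffold-disjoint with near-equal folds", {
  # molecules sharing a scaffold always land in the same fold
  keys <- c(rep("s1", 6), rep("s2", 3), letters[1:20])
  for (seed in 1:5) {
    sp <- scaffold_split(keys, K = 5, seed = seed)
    expect_length(unique(sp$fold_id[keys == "s1"]), 1L)
    expect_length(unique(sp$fold_id[keys == "s2"]), 1L)
    tab <- table(factor(sp$fold_id, levels = 1:5))
    expect_lte(max(tab) - min(tab), 6L)  # largest group size bounds skew
  }
  # 100 singleton scaffolds pack into folds of exactly 20
  sp <- scaffold_split(paste0("u", 1:100), K = 5, seed = 1)
  expect_true(all(table(sp$fold_id) == 20))
  expect_error(scaffold_split(letters[1:10], K = 1), "K must be")
  expect_error(scaffold_split(c("a", "a", "b"), K = 3), "scaffold groups")
})

test_that("the designated test fold has the most distinct scaffolds", {
  set.seed(7)
  for (i in 1:10) {
    keys <- sample(paste0("s", 1:40), 120, replace = TRUE)
    sp <- scaffold_split(keys, K = 4, seed = i)
    distinct <- vapply(1:4, function(f)
      length(unique(keys[sp$fold_id == f])), integer(1))
    expect_equal(distinct[sp$test_fold], max(distinct))
  }
})

test_that("SMILES IO round-trips through CSV, .smi and vocab files", {
  tmp <- withr::local_tempdir()
  smi <- c("CCO", "c1ccccc1")
  utils::write.csv(data.frame(smiles = smi), file.path(tmp, "a.csv"),
                   row.names = FALSE)
  writeLines(paste(smi, c("mol1", "mol2")), file.path(tmp, "a.smi"))
  expect_equal(read_smiles(file.path(tmp, "a.csv")), smi)
  expect_equal(read_smiles(file.path(tmp, "a.smi")), smi)
  v <- build_vocab(smi)
  write_vocab(v, file.path(tmp, "vocab.txt"))
  expect_equal(read_vocab(file.path(tmp, "vocab.txt")), v)
})
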
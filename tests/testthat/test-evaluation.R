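test_that("perplexity hits its analytic fixed points", {
  uni <- matrix(1 / 20, 10, 20)
  expect_equal(perplexity(uni, paste(rep("A", 10), collapse = "")), 20,
               tolerance = 1e-12)
  hot <- matrix(0, 4, 20)
  idx <- seq_to_idx <- match(c("A", "C", "D", "E"), AA_ALPHABET)
  hot[cbind(1:4, idx)] <- 1
  expect_equal(perplexity(hot, "ACDE"), 1, tolerance = 1e-12)
  two <- matrix(1e-3, 2, 20)
  two[1, 1] <- 0.5; two[2, 3] <- 0.125
  expect_equal(perplexity(two, "AD"), 4, tolerance = 1e-12)
  expect_warning(
    perplexity(matrix(c(rep(0, 20)), 1, 20), "A"), "clamped")
})

test_that("recovery counts identities over unmasked positions", {
  expect_equal(recovery("ACDEF", "ACDEF"), 100)
  expect_equal(recovery("AAAAA", "CCCCC"), 0)
  expect_equal(recovery("AAAAAAACCC", "AAAAAAADDD"), 70)
  expect_equal(recovery("ACDEF", "ACDEF", mask = c(TRUE, TRUE, FALSE, FALSE, FALSE)), 100)
  expect_error(recovery("AC", "ACD"), "differ")
})

test_that("composition deviation is exact, scale-free and zero at equality", {
  same <- c("ACDEFGHIKLMNPQRSTVWY")
  cd <- composition_deviation(same, same)
  expect_true(all(cd$rel_dev == 0))
  expect_equal(cd$median_rel_dev, 0)
  # A: native 2/20 = 0.10, designed 3/20 = 0.15 -> deviation 0.5
  nat <- paste(c(rep("A", 2), rep("C", 18)), collapse = "")
  des <- paste(c(rep("A", 3), rep("C", 17)), collapse = "")
  expect_equal(unname(composition_deviation(nat, des)$rel_dev["A"]), 0.5)
  # doubling all counts changes nothing
  expect_equal(composition_deviation(c(nat, nat), c(des, des))$rel_dev,
               composition_deviation(nat, des)$rel_dev)
})

test_that("log-odds confusion is zero under exact independence and near log2(20) on the diagonal for self-substitution", {
  # every ordered pair exactly once: joint = product of marginals
  pairs <- expand.grid(x = AA_ALPHABET, y = AA_ALPHABET)
  nat <- paste(pairs$x, collapse = "")
  des <- paste(pairs$y, collapse = "")
  conf <- confusion_logodds(nat, des)
  expect_lt(max(abs(conf$logodds)), 1e-9)
  expect_equal(sum(conf$joint), 1, tolerance = 1e-9)
  # perfect self-substitution with uniform natives
  m <- 1000L
  self <- paste(rep(AA_ALPHABET, each = m), collapse = "")
  conf2 <- confusion_logodds(self, self)
  expect_equal(unname(diag(conf2$logodds)), rep(log2(20), 20),
               tolerance = 0.05)
  expect_true(all(conf2$logodds[upper.tri(conf2$logodds)] < -5))
  expect_equal(rowSums(conf2$joint), colSums(conf2$joint), tolerance = 1e-9)
})

test_that("confusion of an identity-dominated pool correlates with BLOSUM62", {
  # designs that mostly conserve the native residue produce a
  # diagonal-dominant log-odds matrix, which must correlate positively
  # with BLOSUM62 (whose diagonal is positive)
  set.seed(71)
  nat_c <- sample(AA_ALPHABET, 4000, replace = TRUE)
  des_c <- ifelse(stats::runif(4000) < 0.7, nat_c,
                  sample(AA_ALPHABET, 4000, replace = TRUE))
  conf <- confusion_logodds(paste(nat_c, collapse = ""),
                            paste(des_c, collapse = ""))
  expect_gt(conf$pearson_vs_blosum62, 0.3)
})

test_that("BLOSUM scores self-normalize and match the table on uniform predictions", {
  B <- blosum62()
  hot <- matrix(0, 4, 20)
  idx <- match(c("W", "A", "K", "F"), AA_ALPHABET)
  hot[cbind(1:4, idx)] <- 1
  bs <- blosum_score(hot, "WAKF")
  expect_equal(bs$relative, 1)
  expect_equal(bs$absolute, mean(diag(B)[idx]))
  uni <- matrix(1 / 20, 1, 20)
  bs2 <- blosum_score(uni, "W")
  expect_equal(bs2$absolute, mean(B["W", ]))
  # any prediction stays within the native row's range
  set.seed(72)
  p <- matrix(stats::runif(20), 1, 20); p <- p / sum(p)
  bs3 <- blosum_score(p, "W")
  expect_gte(bs3$absolute, min(B["W", ]))
  expect_lte(bs3$absolute, max(B["W", ]))
})

test_that("hydrophobicity conservation scores class agreement", {
  expect_equal(hydrophobic_conservation("LIVF", "LIVF")$joint, 100)
  expect_equal(hydrophobic_conservation("LLLL", "KKKK")$joint, 0)
  # LKLK -> VKDE: L->V conserved (both hydrophobic), K->K conserved,
  # L->D flipped, K->E conserved (both hydrophilic)
  hc <- hydrophobic_conservation("LKLK", "VKDE")
  expect_equal(hc$joint, 75)
  expect_equal(hc$hydrophobic, 50)
  expect_equal(hc$hydrophilic, 100)
})

test_that("homopolymer windows are fully low complexity and diverse windows are not", {
  res <- seg_lcr(paste(rep("A", 12), collapse = ""))
  expect_equal(res$lcr, 100)
  expect_equal(nrow(res$segments), 1L)
  expect_equal(res$segments$start, 1L)
  expect_equal(res$segments$end, 12L)
  distinct <- paste(AA_ALPHABET[1:12], collapse = "")
  expect_equal(seg_lcr(distinct)$lcr, 0)
  # entropy of 12 distinct letters is log2(12) > 2.2 (checked directly)
  expect_gt(log2(12), 2.2)
  # shorter than one window: no segments
  expect_equal(seg_lcr("ACD")$lcr, 0)
})

test_that("low-complexity detection agrees with an independent reimplementation on 100 sequences", {
  set.seed(73)
  seqs <- character(0)
  for (i in 1:50)   # uniform-random sequences
    seqs <- c(seqs, paste(sample(AA_ALPHABET, sample(15:60, 1),
                                 replace = TRUE), collapse = ""))
  for (i in 1:50) { # repeat-rich sequences
    core <- sample(AA_ALPHABET, 3)
    seqs <- c(seqs, paste(sample(c(sample(AA_ALPHABET, 10, TRUE),
                                   rep(core, sample(4:12, 1)))),
                          collapse = ""))
  }
  for (sq in seqs) {
    got <- seg_lcr(sq)
    ref <- oracle_seg(sq)
    expect_equal(got$lcr, ref$lcr, tolerance = 1e-9, label = sq)
    if (is.null(ref$segments)) {
      expect_equal(nrow(got$segments), 0L)
    } else {
      expect_equal(unname(as.matrix(got$segments)),
                   unname(ref$segments), label = sq)
    }
  }
})

test_that("random sequences have less low complexity than homopolymer-rich ones", {
  set.seed(74)
  lcr_rand <- lcr_homo <- numeric(10)
  for (i in 1:10) {
    L <- 40L
    lcr_rand[i] <- seg_lcr(paste(sample(AA_ALPHABET, L, TRUE),
                                 collapse = ""))$lcr
    homo <- c(sample(AA_ALPHABET, L - 20, TRUE), rep("Q", 20))
    lcr_homo[i] <- seg_lcr(paste(sample(homo), collapse = ""))$lcr
  }
  expect_lt(mean(lcr_rand), mean(lcr_homo))
})

test_that("extended peptides are entirely surface and classification is rigid-motion invariant", {
  bb <- make_backbone(synthetic_spec(data.frame(type = "strand", length = 8),
                                     seed = 1L))
  seq8 <- "ACDEFGHI"
  cls <- rsa_classify(bb, seq8)
  expect_true(all(cls$rsa > 0.2))
  expect_true(all(cls$class == "surface"))
  # the sphere-point grid does not rotate with the molecule, so numerical
  # SASA varies slightly under rotation; the classification must not
  moved <- transform_backbone(bb, random_rotation(75L), c(10, 0, -5))
  moved_cls <- rsa_classify(moved, seq8)
  expect_identical(moved_cls$class, cls$class)
  expect_equal(moved_cls$rsa, cls$rsa, tolerance = 0.05)
  # boundary: RSA exactly at the threshold is surface (strictly-below rule)
  expect_identical(ifelse(0.2 < 0.2, "core", "surface"), "surface")
  expect_warning(rsa_classify(bb, "ACDEFGHX"), "unknown")
})

test_that("buried residues of a compact fold classify as core", {
  bb <- fixture_backbone(seed = 76L, lengths = c(12, 10, 8))
  cls <- rsa_classify(bb, bb$native_seq)
  expect_true(all(is.finite(cls$rsa)))
  expect_gt(stats::sd(cls$rsa), 0)   # both buried and exposed environments
})

test_that("Kabsch RMSD is zero for rigid copies, symmetric, and matches the reference fit", {
  bb <- fixture_coil(10, seed = 77L)
  P <- bb$ca
  Q <- sweep(P %*% t(random_rotation(78L)), 2, c(4, 5, 6), "+")
  expect_lt(kabsch_rmsd(P, Q), 1e-6)
  Q2 <- Q; Q2[4, ] <- Q2[4, ] + c(0, 0, 3)
  r <- kabsch_rmsd(P, Q2)
  expect_equal(r, kabsch_rmsd(Q2, P), tolerance = 1e-9)
  # independent oracle: the reference superposition from bio3d
  ref <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q2)), fit = TRUE)
  expect_equal(r, ref, tolerance = 1e-3)   # the reference rounds its output
  expect_lte(r, ref + 1e-9)                # and ours is never worse
  expect_error(kabsch_rmsd(P, Q2[1:5, ]), "differ")
})

test_that("GDT-TS hits its analytic fixed points", {
  bb <- fixture_coil(20, seed = 79L)
  P <- bb$ca
  expect_equal(gdt_ts(P, P), 100)
  Q <- sweep(P %*% t(random_rotation(80L)), 2, c(1, 2, 3), "+")
  expect_equal(gdt_ts(P, Q), 100, tolerance = 1e-9)
  # uniform 1.5 A displacement of half the atoms: the least-squares
  # compromise translation (0.75 A) brings every pair under 1 A
  Qh <- P; Qh[11:20, 3] <- Qh[11:20, 3] + 1.5
  expect_equal(gdt_ts(P, Qh), 100, tolerance = 1e-9)
  # 3 A displacement: cutoff 1 can hold only one half (displacement > 2
  # cutoffs), cutoffs 2, 4, 8 hold everything via the 1.5 A compromise
  Q3 <- P; Q3[11:20, 3] <- Q3[11:20, 3] + 3
  expect_equal(gdt_ts(P, Q3), mean(c(50, 100, 100, 100)), tolerance = 1e-6)
})

test_that("native self-evaluation is a fixed point of the full battery", {
  ds <- learnability_dataset(3, 25, seed = 400)
  natives <- vapply(ds, function(s) s$native_seq, character(1))
  hot <- lapply(ds, function(s) {
    P <- matrix(0, s$length, 20)
    P[cbind(seq_len(s$length), seq_to_idx(s$native_seq))] <- 1
    P
  })
  rep_ <- evaluate_designs(natives, natives, predictions = hot,
                           structures = ds)
  expect_equal(rep_$aggregate$median_recovery, 100)
  expect_equal(rep_$aggregate$pooled_recovery, 100)
  expect_equal(rep_$aggregate$median_rel_dev, 0)
  expect_equal(rep_$aggregate$median_rel_blosum, 1.0)
  expect_equal(rep_$aggregate$median_hydro, 100)
  expect_equal(rep_$aggregate$perplexity, 1, tolerance = 1e-9)
  expect_equal(rep_$aggregate$mean_lcr_native, rep_$aggregate$mean_lcr_design)
  # report files
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_metrics_report(rep_, tsv, js)
  expect_true(file.exists(tsv) && file.exists(js))
  agg <- jsonlite::read_json(js)
  expect_equal(agg$median_recovery, 100)
})
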
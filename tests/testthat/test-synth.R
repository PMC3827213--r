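test_that("templates carry the planted class markers", {
  tpl <- class_templates()
  recs <- seq_records(names(tpl), vapply(tpl, `[[`, "", "sequence"))
  expect_true(all(recs$length == 160L))
  sig <- scan_pattern(CYANOPHAGE_SIGNATURE, recs)
  expect_equal(sig$sequence_id, "cyanophage")
  expect_equal(sig$start, 57L)
  for (cl in names(tpl)) {
    ann <- manual_annotation(cl, 160L, 55L, 146L, l57 = c(109L, 121L),
                             beta7 = 126L)
    rec <- recs[recs$id == cl, ]
    expect_true(beta7_residue(rec, ann)$is_R)
    expect_true(any(acidic_partners(rec, ann)$at_117))
    dbl <- find_doublets(rec, ann)
    expect_equal(unique(dbl$kind), tpl[[cl]]$features$doublet_kind)
    cams <- find_cam(rec, ann)
    if (tpl[[cl]]$features$cam_kind != "none") {
      expect_true(tpl[[cl]]$features$cam_kind %in% cams$kind)
    }
  }
})

test_that("the generating tree plants one clade per class", {
  cfg <- small_config(n = 5L, seed = 2L)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 20L)
  for (cl in names(cfg$n_per_class)) {
    expect_true(is_monophyletic(tr, grep(paste0("^", cl, "_"),
                                         tr$tip.label, value = TRUE)))
  }
  # same seed -> identical newick
  expect_identical(ape::write.tree(simulate_tree(cfg)),
                   ape::write.tree(simulate_tree(cfg)))
})

test_that("leaf counts equal the configured taxa over random configs", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(1:8, 4, replace = TRUE)
    if (sum(n) < 3L) next
    cfg <- simulation_config(
      n_per_class = stats::setNames(n, cyanoshsp:::SHSP_CLASSES),
      seed = rep)
    tr <- simulate_tree(cfg)
    expect_equal(length(tr$tip.label), sum(n))
    fam <- evolve_family(tr, cfg)
    expect_equal(nrow(fam$records), sum(n))
    expect_equal(unname(table(fam$truth$class)[cyanoshsp:::SHSP_CLASSES]),
                 n, ignore_attr = TRUE)
  }
})

test_that("mu = 0 reproduces the class template at every leaf", {
  cfg <- small_config(n = 4L, mu = 0, seed = 3L)
  fam <- simulate_family(cfg)
  tpl <- class_templates()
  for (i in seq_len(nrow(fam$records))) {
    cl <- sub("_[0-9]+$", "", fam$records$id[i])
    expect_identical(fam$records$residues[i], tpl[[cl]]$sequence)
  }
})

test_that("fixed seeds give byte-identical families", {
  cfg <- small_config(n = 5L, seed = 99L)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$truth, f2$truth)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(f1$records, p1)
  write_fasta(f2$records, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("per-branch substitution proportion matches the binomial model", {
  set.seed(17)
  mu <- 0.05
  L <- 150L
  n_rep <- 100L
  diffs <- vapply(seq_len(n_rep), function(r) {
    chars <- strsplit(random_protein(L), "")[[1]]
    sum(cyanoshsp:::mutate_seq(chars, mu, 1, integer(0)) != chars)
  }, numeric(1))
  total <- sum(diffs)
  n <- L * n_rep
  # 99% binomial interval around mu
  half <- stats::qnorm(0.995) * sqrt(n * mu * (1 - mu))
  expect_gt(total, n * mu - half)
  expect_lt(total, n * mu + half)
})

test_that("rho = 0 preserves every planted marker at high divergence", {
  cfg <- small_config(n = 8L, mu = 0.1, rho = 0, seed = 23L)
  fam <- simulate_family(cfg)
  cyan <- fam$records[grepl("^cyanophage_", fam$records$id), ]
  sig <- scan_pattern(CYANOPHAGE_SIGNATURE, cyan)
  expect_true(all(cyan$id %in% sig$sequence_id))
  # planted truth coordinates re-validate: doublet residues intact
  for (i in seq_len(nrow(fam$records))) {
    row <- fam$truth[fam$truth$taxon == fam$records$id[i], ]
    two <- substring(fam$records$residues[i], row$doublet_pos,
                     row$doublet_pos + 1L)
    expect_equal(two, if (row$doublet_kind == "doublet_AG") "AG" else "PG")
    expect_equal(substring(fam$records$residues[i], row$beta7_pos,
                           row$beta7_pos), "R")
  }
})

test_that("indels change lengths only when enabled", {
  cfg0 <- small_config(n = 3L, seed = 5L)
  expect_true(all(simulate_family(cfg0)$records$length == 160L))
  cfg1 <- small_config(n = 3L, seed = 5L, indel_rate = 0.02)
  lens <- simulate_family(cfg1)$records$length
  expect_true(any(lens != 160L))
})
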
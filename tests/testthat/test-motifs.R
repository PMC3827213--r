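test_that("constructed CAMs are found in the C-terminal extension", {
  # record = 92-residue ACD-like core + extension "AALAVAA"
  rec <- seq_records("c1", paste0(strrep("Q", 92), "AALAVAA"))
  ann <- manual_annotation("c1", 99L, 1L, 92L)
  hits <- find_cam(rec, ann)
  cl <- hits[hits$kind == "cam_classical", ]
  expect_equal(cl$positions, "95,97")  # L and V, positions 3 and 5 of the ext
  expect_equal(cl$residues, "LV")
  expect_true(all(hits$region == "c_ext"))

  rec2 <- seq_records("c2", paste0(strrep("Q", 92), "IAVAL"))
  hits2 <- find_cam(rec2, manual_annotation("c2", 97L, 1L, 92L))
  tri <- hits2[hits2$kind == "cam_triple", ]
  expect_equal(tri$positions, "93,95,97")
  expect_equal(tri$residues, "IVL")
})

test_that("a triple does not suppress contained pair motifs", {
  # ext "LAVAL": classical L-A-V at (1,3) and V-A-L triple-compatible pairs
  rec <- seq_records("c3", paste0(strrep("Q", 92), "VALAL"))
  hits <- find_cam(rec, manual_annotation("c3", 97L, 1L, 92L))
  expect_true("cam_triple" %in% hits$kind)
  expect_true("cam_classical" %in% hits$kind)
})

test_that("an empty extension yields no CAM hits", {
  rec <- seq_records("c4", strrep("Q", 92))
  ann <- manual_annotation("c4", 92L, 1L, 92L)
  expect_null(ann$c_ext)
  expect_equal(nrow(find_cam(rec, ann)), 0L)
})

test_that("doublets carry hydrophobic/aromatic context flags", {
  s <- paste0(strrep("Q", 40), "LAGF", strrep("Q", 20), "PGK",
              strrep("Q", 33))
  rec <- seq_records("d1", s)
  ann <- manual_annotation("d1", nchar(s), 11L, 90L)
  hits <- find_doublets(rec, ann)
  ag <- hits[hits$kind == "doublet_AG", ]
  pg <- hits[hits$kind == "doublet_PG", ]
  expect_equal(ag$start, 42L)
  expect_true(ag$preceded_by_L)
  expect_true(ag$followed_by_aromatic)
  expect_equal(pg$start, 65L)
  expect_false(pg$preceded_by_L)
  expect_false(pg$followed_by_aromatic)
  none <- find_doublets(seq_records("d2", strrep("Q", 100)),
                        manual_annotation("d2", 100L, 11L, 90L))
  expect_equal(nrow(none), 0L)
})

test_that("doublet search is confined to the ACD plus its 10-residue flanks", {
  s <- paste0("AG", strrep("Q", 38), "AG", strrep("Q", 60), "AG")
  rec <- seq_records("d3", s)
  ann <- manual_annotation("d3", nchar(s), 31L, 80L)
  hits <- find_doublets(rec, ann)
  expect_equal(hits$start, 41L)  # the first and last AG fall outside
})

test_that("the beta7 column residue is reported with basicity flags", {
  tpl <- class_templates()$cyanophage$sequence
  rec <- seq_records("b1", tpl)
  ann <- manual_annotation("b1", 160L, 55L, 146L, beta7 = 126L)
  hit <- beta7_residue(rec, ann)
  expect_equal(hit$residues, "R")
  expect_true(hit$is_R)
  expect_true(hit$is_basic)
  expect_false(hit$is_N)
  # a lysine variant is basic but not R; an asparagine is neither
  for (sub in list(c("K", TRUE), c("N", FALSE))) {
    chars <- strsplit(tpl, "")[[1]]
    chars[126] <- sub[1]
    h <- beta7_residue(seq_records("b", paste(chars, collapse = "")),
                       manual_annotation("b", 160L, 55L, 146L, beta7 = 126L))
    expect_equal(h$residues, sub[1])
    expect_equal(h$is_basic, as.logical(sub[2]))
    expect_false(h$is_R)
  }
})

test_that("acidic L57 partners are enumerated with the 117 flag", {
  # loop occupies sequence positions 109-121 when the arm is 54 residues
  chars <- strsplit(class_templates()$cyanophage$sequence, "")[[1]]
  chars[109:121] <- strsplit("DADEDQQQQQQQQ", "")[[1]]
  rec <- seq_records("a1", paste(chars, collapse = ""))
  ann <- manual_annotation("a1", 160L, 55L, 146L, l57 = c(109L, 121L))
  hits <- acidic_partners(rec, ann)
  expect_equal(nrow(hits), 4L)  # D, D, E, D
  expect_equal(hits$start, c(109L, 111L, 112L, 113L))
  expect_equal(hits$ref_column, c(109L, 111L, 112L, 113L))
  expect_false(any(hits$at_117))
  # single E at reference column 117
  chars[109:121] <- strsplit("QQQQQQQQEQQQQ", "")[[1]]
  hits2 <- acidic_partners(seq_records("a2", paste(chars, collapse = "")),
                           manual_annotation("a2", 160L, 55L, 146L,
                                             l57 = c(109L, 121L)))
  expect_equal(nrow(hits2), 1L)
  expect_true(hits2$at_117)
  # no acidic residue at all
  chars[109:121] <- strsplit("QQQQQQQQQQQQQ", "")[[1]]
  hits3 <- acidic_partners(seq_records("a3", paste(chars, collapse = "")),
                           manual_annotation("a3", 160L, 55L, 146L,
                                             l57 = c(109L, 121L)))
  expect_equal(nrow(hits3), 0L)
})

test_that("CAM and doublet finders equal brute-force window enumeration", {
  set.seed(55)
  for (rep in 1:200) {
    L <- sample(100:140, 1)
    acd_end <- sample(70:(L - 1), 1)
    s <- random_protein(L)
    chars <- strsplit(s, "")[[1]]
    rec <- seq_records("r", s)
    ann <- manual_annotation("r", L, 20L, acd_end)
    cams <- find_cam(rec, ann)
    expect_identical(hit_key(cams),
                     brute_key(brute_cam(chars, acd_end + 1L, L)))
    expect_true(all(cams$region == "c_ext"))
    dbl <- find_doublets(rec, ann)
    expect_identical(
      hit_key(dbl),
      brute_key(brute_doublets(chars, max(1L, 20L - 10L),
                               min(L, acd_end + 10L))))
  }
})
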
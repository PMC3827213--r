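# Shared generators and independent brute-force oracles.

AA <- cyanoshsp:::AA20

random_protein <- function(len) {
  paste(sample(AA, len, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(30L, 200L)) {
  seq_records(id = sprintf("r%03d", seq_len(n)),
              residues = vapply(seq_len(n), function(i) {
                random_protein(sample(len_range[1]:len_range[2], 1))
              }, character(1)))
}

# Element-by-element pattern-matching oracle, independent of the regex
# engine used by scan_pattern(). X matches only wildcard elements.
brute_scan <- function(pattern, seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  w <- pattern$width
  if (L < w) return(integer(0))
  starts <- integer(0)
  for (st in seq_len(L - w + 1L)) {
    pos <- st
    ok <- TRUE
    for (el in pattern$elements) {
      if (el$type == "wild") {
        pos <- pos + el$n
      } else {
        if (!chars[pos] %in% el$residues) { ok <- FALSE; break }
        pos <- pos + 1L
      }
    }
    if (ok) starts <- c(starts, st)
  }
  starts
}

random_pattern <- function() {
  nel <- sample(3:6, 1)
  els <- character(nel)
  for (i in seq_len(nel)) {
    kind <- sample(c("fixed", "class", "wild"), 1,
                   prob = c(0.45, 0.35, 0.2))
    els[i] <- switch(kind,
      fixed = sample(AA, 1),
      class = paste0("[", paste(sample(AA, sample(2:4, 1)), collapse = ""), "]"),
      wild = if (stats::runif(1) < 0.5) "x"
             else sprintf("x(%d)", sample(2:6, 1)))
  }
  parse_pattern(paste(els, collapse = "-"))
}

# Manual region annotation for motif tests (bypasses profile placement).
manual_annotation <- function(id, len, acd_start, acd_end,
                              l57 = NULL, beta7 = NA_integer_,
                              acd_ref_start = 55L) {
  structure(list(sequence_id = id, acd_start = acd_start, acd_end = acd_end,
                 n_arm = if (acd_start > 1L) c(1L, acd_start - 1L) else NULL,
                 c_ext = if (acd_end < len) c(acd_end + 1L, len) else NULL,
                 strand_map = NULL, l57_interval = l57,
                 beta7_arg_pos = beta7, acd_ref_start = acd_ref_start,
                 acd_score = 0, length = len),
            class = "region_annotation")
}

# Brute-force window enumerators for every CAM kind and the doublets.
ILV <- c("I", "L", "V")
brute_cam <- function(chars, lo, hi) {
  out <- list()
  add <- function(kind, pos) {
    out[[length(out) + 1L]] <<- list(kind = kind, pos = pos)
  }
  if (!is.null(lo) && hi - lo >= 2L) {
    for (i in lo:(hi - 2L)) {
      if (chars[i] == "L" && chars[i + 2] %in% ILV)
        add("cam_classical", c(i, i + 2))
      if (chars[i] == "A" && chars[i + 2] == "P") add("cam_AXP", c(i, i + 2))
      if (chars[i] == "L" && chars[i + 2] == "G") add("cam_LXG", c(i, i + 2))
      if (chars[i] == "L" && chars[i + 2] == "A") add("cam_LXA", c(i, i + 2))
      if (i + 4 <= hi && chars[i] %in% c("I", "V") &&
          chars[i + 2] %in% ILV && chars[i + 4] %in% ILV)
        add("cam_triple", c(i, i + 2, i + 4))
    }
  }
  out
}

brute_doublets <- function(chars, lo, hi) {
  out <- list()
  if (hi - lo >= 1L) {
    for (i in lo:(hi - 1L)) {
      two <- paste0(chars[i], chars[i + 1])
      if (two %in% c("AG", "PG")) {
        out[[length(out) + 1L]] <- list(
          kind = if (two == "AG") "doublet_AG" else "doublet_PG",
          pos = c(i, i + 1L))
      }
    }
  }
  out
}

hit_key <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  sort(paste(hits$kind, hits$positions, sep = "@"))
}

brute_key <- function(brute) {
  if (length(brute) == 0L) return(character(0))
  sort(vapply(brute, function(h) {
    paste(h$kind, paste(h$pos, collapse = ","), sep = "@")
  }, character(1)))
}

# Exhaustive global affine-gap alignment score by path enumeration
# (gap of length L costs open + L * extend; terminal gaps included).
enum_align_score <- function(a, b, submat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > length(av) && j > length(bv)) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1L, j + 1L, "M", sc + submat[av[i], bv[j]])
    }
    if (i <= length(av)) {
      rec(i + 1L, j, "GA",
          sc - gap_extend - if (prev == "GA") 0 else gap_open)
    }
    if (j <= length(bv)) {
      rec(i, j + 1L, "GB",
          sc - gap_extend - if (prev == "GB") 0 else gap_open)
    }
  }
  rec(1L, 1L, "S", 0)
  best
}

# All bipartitions of a tree via phangorn, as sorted tip-index sets.
splits_oracle <- function(tree) {
  m <- as.matrix(phangorn::as.splits(tree))
  lapply(seq_len(nrow(m)), function(i) sort(unname(which(m[i, ] == 1))))
}

label_map <- c(cyanophage = "cyanophage_like",
               bacterial_class_A = "bacterial_class_A_like",
               class_B_plant = "class_B_plant_like",
               cyanobacterial = "cyanobacterial_like")

small_config <- function(n = 6L, seed = 1L, mu = 0.05, rho = 0.1, ...) {
  simulation_config(n_per_class = c(cyanophage = n, bacterial_class_A = n,
                                    class_B_plant = n, cyanobacterial = n),
                    mu = mu, rho = rho, seed = seed, ...)
}
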
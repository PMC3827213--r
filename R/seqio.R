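#' @importFrom utils read.delim write.table
NULL

#' Construct a set of protein sequence records
#'
#' Records are a plain data frame with columns `id`, `description` and
#' `residues`. Residues are uppercase letters over the 20 amino acids plus
#' `X`; gap characters are never allowed. Ids must be unique.
#'
#' @param id Character vector of non-empty, unique identifiers.
#' @param residues Character vector of residue strings (same length as `id`).
#' @param description Optional free-text descriptions (default empty).
#' @param strict If `TRUE` (default), residues outside the 20-letter alphabet
#'   plus `X` are an error; if `FALSE`, alphabetic ambiguity codes are mapped
#'   to `X` (gaps and non-letters are always an error).
#' @return A data frame with columns `id`, `description`, `residues`, `length`.
#' @export
seq_records <- function(id, residues, description = "", strict = TRUE) {
  stopifnot(is.character(id), is.character(residues),
            length(id) == length(residues))
  if (length(id) == 0L) stop("no sequence records")
  if (any(!nzchar(id))) stop("empty sequence id")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  residues <- toupper(residues)
  if (any(!nzchar(residues))) stop("zero-length sequence")
  bad <- grepl("[-.*]", residues)
  if (any(bad)) stop("gap or stop characters in sequence(s): ",
                     paste(id[bad], collapse = ", "))
  ok <- paste0("[", paste(c(AA20, "X"), collapse = ""), "]")
  nonstd <- gsub(ok, "", residues)
  if (any(nzchar(nonstd))) {
    if (strict) {
      stop("illegal residue characters (",
           paste(unique(strsplit(paste(nonstd, collapse = ""), "")[[1]]),
                 collapse = ""),
           ") in: ", paste(id[nzchar(nonstd)], collapse = ", "))
    }
    nonletter <- gsub("[A-Z]", "", nonstd)
    if (any(nzchar(nonletter))) stop("non-letter residue characters")
    residues <- vapply(residues, function(s) {
      chars <- strsplit(s, "")[[1]]
      chars[!chars %in% c(AA20, "X")] <- "X"
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  description <- rep_len(as.character(description), length(id))
  data.frame(id = id, description = description, residues = residues,
             length = nchar(residues), stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param strict See [seq_records()].
#' @return A record data frame (see [seq_records()]); input order preserved.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq_records(id = id, residues = as.character(aa), description = desc,
              strict = strict)
}

#' Write records to FASTA
#'
#' Output is deterministic: fixed wrap width, `>id description` headers.
#'
#' @param records Record data frame.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("no records to write")
  }
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- if (nzchar(records$description[i])) {
      paste0(">", records$id[i], " ", records$description[i])
    } else {
      paste0(">", records$id[i])
    }
    s <- records$residues[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Load a packaged sHSP catalog table
#'
#' Catalogs are UTF-8 TSVs with columns `organism`, `accession`, `label`,
#' `group` and (for host genomes) `gene_count`. Groups are cross-checked
#' against the nomenclature prefix: `HspSP-` marks *Synechococcus*-phage,
#' `HspPP-` *Prochlorococcus*-phage and `HspS-` *Synechococcus*-host entries.
#' For hosts, the number of accessions listed per organism must equal the
#' recorded gene count.
#'
#' @param path Path to a catalog TSV; see [catalog_path()] for the packaged
#'   tables.
#' @return Data frame with one row per accession.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("organism", "accession", "label", "group")
  if (!all(need %in% names(tab))) {
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  }
  if (!"gene_count" %in% names(tab)) tab$gene_count <- NA_integer_
  if (any(!nzchar(tab$accession))) stop("empty accession in catalog")
  if (anyDuplicated(tab$accession)) stop("duplicate accession in catalog")
  derived <- ifelse(startsWith(tab$label, "HspSP-"), "synechococcus_phage",
             ifelse(startsWith(tab$label, "HspPP-"), "prochlorococcus_phage",
             ifelse(startsWith(tab$label, "HspS-"), "synechococcus_host",
                    NA_character_)))
  if (anyNA(derived)) {
    stop("unknown nomenclature prefix: ",
         paste(tab$label[is.na(derived)], collapse = ", "))
  }
  if (!all(derived == tab$group)) stop("group column disagrees with prefix")
  hosts <- tab[tab$group == "synechococcus_host", ]
  if (nrow(hosts) > 0L) {
    if (anyNA(hosts$gene_count)) stop("host rows need gene_count")
    per_org <- table(hosts$organism)
    declared <- tapply(hosts$gene_count, hosts$organism, unique)
    if (any(vapply(declared, length, 1L) != 1L)) {
      stop("inconsistent gene_count within an organism")
    }
    mism <- names(per_org)[as.integer(per_org) != unlist(declared)[names(per_org)]]
    if (length(mism) > 0L) {
      stop("accession count != gene_count for: ", paste(mism, collapse = ", "))
    }
  }
  tab
}

#' Path to a packaged data file
#'
#' @param name One of `"cyanophage_catalog.tsv"`, `"host_catalog.tsv"`,
#'   `"acd_reference_synthetic.fasta"`, `"reference_map_synthetic.tsv"`.
#' @return Absolute path inside the installed package.
#' @export
catalog_path <- function(name) {
  p <- system.file("extdata", name, package = "cyanoshsp")
  if (!nzchar(p)) stop("no packaged file named ", name)
  p
}
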
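#' Fetch catalog protein sequences from NCBI (network-gated)
#'
#' Resolves the accessions of a packaged catalog to sequences via the NCBI
#' efetch service and writes them to a FASTA file. This is the only
#' network-touching operation in the package; every other function works
#' offline. Records are re-keyed by accession.
#'
#' @param catalog Catalog data frame (see [load_catalog()]).
#' @param dest Output FASTA path.
#' @param base_url efetch endpoint (exposed for testing against a mirror).
#' @param batch_size Accessions per request (default 50).
#' @return The record data frame, invisibly also written to `dest`.
#' @export
fetch_catalog_sequences <- function(catalog, dest,
                                    base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                                    batch_size = 50L) {
  stopifnot(is.data.frame(catalog), "accession" %in% names(catalog))
  acc <- unique(catalog$accession)
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  chunks <- split(acc, ceiling(seq_along(acc) / batch_size))
  parts <- character(0)
  for (ch in chunks) {
    url <- paste0(base_url, "?db=protein&rettype=fasta&retmode=text&id=",
                  paste(ch, collapse = ","))
    status <- tryCatch(utils::download.file(url, tmp, quiet = TRUE,
                                            mode = "wb"),
                       error = function(e) {
                         stop("could not fetch sequences from NCBI ",
                              "(network unavailable?): ",
                              conditionMessage(e), call. = FALSE)
                       })
    if (status != 0L) stop("efetch request failed with status ", status)
    parts <- c(parts, readLines(tmp))
  }
  writeLines(parts, dest)
  recs <- read_fasta(dest, strict = FALSE)
  # efetch ids look like "YP_195165.1" or "ref|YP_195165.1|"
  recs$id <- sub("^.*\\|([^|]+)\\|.*$", "\\1", recs$id)
  missing_acc <- setdiff(acc, recs$id)
  if (length(missing_acc) > 0L) {
    warning("accessions not returned: ", paste(missing_acc, collapse = ", "))
  }
  write_fasta(recs, dest)
  invisible(recs)
}
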
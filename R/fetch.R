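#' Download a deposited WGS assembly from the ENA public archive
#'
#' Fetches the FASTA of a whole-genome-shotgun (WGS) set by its master
#' accession (e.g. `"JACSEA000000000"`) from the ENA WGS FTP mirror, so
#' published assembly statistics can be recomputed from the deposited
#' sequence. Requires network access; the download is ~50 Mb gzipped per
#' assembly.
#'
#' @param accession WGS master accession (12-15 characters, prefix +
#'   zero-padded version/serial, e.g. `"JACSEA000000000"`).
#' @param dest_dir Directory for the downloaded `.fasta.gz` (default
#'   [tempdir()]); an existing file is reused.
#' @param timeout Download timeout in seconds (default 600).
#' @return Path to the downloaded gzipped FASTA.
#' @export
fetch_wgs_fasta <- function(accession, dest_dir = tempdir(), timeout = 600) {
  prefix <- regmatches(accession, regexpr("^[A-Z]{4,6}", accession))
  if (length(prefix) == 0L) stop("not a WGS accession: ", accession)
  set_id <- paste0(prefix, "01")
  url <- sprintf("https://ftp.ebi.ac.uk/pub/databases/ena/wgs/public/%s/%s.fasta.gz",
                 tolower(substr(prefix, 1L, 3L)), set_id)
  dest <- file.path(dest_dir, paste0(set_id, ".fasta.gz"))
  if (!file.exists(dest)) {
    old <- options(timeout = timeout)
    on.exit(options(old))
    status <- tryCatch(utils::download.file(url, dest, mode = "wb", quiet = TRUE),
                       error = function(e) {
                         unlink(dest)
                         stop("download of ", url, " failed: ",
                              conditionMessage(e), call. = FALSE)
                       })
    if (!identical(status, 0L)) {
      unlink(dest)
      stop("download of ", url, " failed with status ", status)
    }
  }
  dest
}
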
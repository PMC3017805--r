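#' Read a FASTA file into a transcript table
#'
#' Records are returned in file order with sequences normalized to upper
#' case. The collection is the package's shared sequence model: a
#' `data.frame` with columns `id`, `seq` and `description`, used for both
#' FL-cDNAs and ESTs.
#'
#' @param path path to a FASTA file.
#' @param allow_gaps accept `-` characters (aligned FASTA).
#' @return `data.frame` with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA header found in ", path)
  pre <- lines[seq_len(hdr[1] - 1L)]
  if (any(nzchar(trimws(pre))))
    stop("sequence data before first header at line ",
         which(nzchar(trimws(pre)))[1])
  ends <- c(hdr[-1] - 1L, length(lines))
  ids <- character(length(hdr)); descs <- character(length(hdr))
  seqs <- character(length(hdr))
  for (k in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[k]])
    ids[k] <- sub("\\s.*$", "", h)
    descs[k] <- if (grepl("\\s", h)) sub("^\\S+\\s+", "", h) else ""
    if (!nzchar(ids[k])) stop("empty FASTA header at line ", hdr[k])
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    if (hdr[k] + 1L > ends[k]) body <- character(0)
    s <- toupper(paste(trimws(body), collapse = ""))
    if (!nzchar(s)) stop("empty sequence for record '", ids[k],
                         "' at line ", hdr[k])
    pattern <- if (allow_gaps) "[^ACGTN-]" else "[^ACGTN]"
    if (grepl(pattern, s))
      stop("non-ACGTN character in record '", ids[k], "'")
    seqs[k] <- s
  }
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[anyDuplicated(ids)])
  transcript_records(ids, seqs, descs)
}

#' Construct a transcript record table
#'
#' @param id,seq,description character vectors of equal length
#'   (`description` may be omitted).
#' @return `data.frame` with columns `id`, `seq`, `description`.
#' @export
transcript_records <- function(id, seq, description = "") {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) stop("duplicate record id")
  if (any(!nzchar(seq))) stop("empty sequence")
  data.frame(id = as.character(id), seq = toupper(as.character(seq)),
             description = rep_len(as.character(description), length(id)),
             stringsAsFactors = FALSE)
}

#' Write records as FASTA
#'
#' Sequences are wrapped at 60 columns so output is byte-stable.
#'
#' @param records record table from [read_fasta()] / [transcript_records()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[k]))
      paste(records$id[k], records$description[k]) else records$id[k]
    writeLines(paste0(">", hdr), con)
    s <- records$seq[k]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Filter reads by minimum length
#'
#' Single-pass EST reads shorter than `min_len` nucleotides are dropped,
#' mirroring the usual post-trimming acceptance rule for 5' reads
#' (at least 100 consecutive nucleotides).
#'
#' @param reads record table.
#' @param min_len minimum length kept (default 100).
#' @return Filtered record table; the number removed is reported via
#'   `attr(, "n_removed")`.
#' @export
length_filter <- function(reads, min_len = 100) {
  keep <- nchar(reads$seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}
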
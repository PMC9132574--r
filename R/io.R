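## Readers and writers for the plain-text formats the pipeline touches:
## gene FASTA (Prodigal-style headers), cluster membership TSV (MMseqs2
## dialect: representative<TAB>member), and the three tiers of homology
## evidence (domain / homolog / profile hit tables).

.hit_columns <- list(
  domain  = c("gene_id", "domain", "clan", "env_start", "env_end",
              "i_evalue", "coverage", "terminal_variant"),
  homolog = c("query", "target", "evalue", "bitscore", "query_cov",
              "target_cov", "target_annotation", "target_is_duf"),
  profile = c("query_gc", "target_gc", "probability", "score",
              "aligned_cols", "query_cov", "target_cov")
)

#' Read predicted genes from a FASTA file
#'
#' Headers are expected to follow the Prodigal convention
#' `id # start # end # strand # key=value;...`; gene completeness is taken
#' from the `partial=` token (`partial=00` means both ends intact). A record
#' without the token is treated as incomplete, with a warning. Optional
#' `origin=` and `contig=` tokens are parsed when present.
#'
#' @param path Path to an amino-acid FASTA file.
#' @return A `data.frame` of class `gc_genes` with columns `id`, `sequence`,
#'   `is_complete`, `origin`, `contig`, `start`, `end`, `strand`, `flags`.
#' @export
read_genes <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) return(.empty_genes())
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("malformed FASTA: first record does not start with '>' (", first, ")")
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  id <- sub("\\s.*$", "", headers)
  if (anyDuplicated(id))
    stop("duplicate gene id in FASTA: ", id[duplicated(id)][1])
  parse_tok <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=[^;# ]+"), h))
    ifelse(lengths(regmatches(h, gregexpr(paste0(key, "="), h))) > 0 &
             nzchar(m), sub(paste0("^", key, "="), "", m), NA_character_)
  }
  partial <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("partial=[0-9]+", h))
    if (length(m) == 0) NA_character_ else sub("partial=", "", m)
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(partial))
    warning(sum(is.na(partial)), " record(s) without a partial= token; ",
            "treated as incomplete")
  coord <- strsplit(headers, "\\s+#\\s+")
  get_field <- function(i) vapply(coord, function(x)
    if (length(x) >= i) x[i] else NA_character_, character(1))
  origin <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("origin=[^;# ]+", h))
    if (length(m)) sub("origin=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  contig <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("contig=[^;# ]+", h))
    if (length(m)) sub("contig=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  g <- data.frame(
    id = id,
    sequence = as.character(seqs),
    is_complete = !is.na(partial) & partial == "00",
    origin = origin,
    contig = contig,
    start = suppressWarnings(as.integer(get_field(2))),
    end = suppressWarnings(as.integer(get_field(3))),
    strand = ifelse(get_field(4) %in% c("1", "+"), "+",
                    ifelse(get_field(4) %in% c("-1", "-"), "-", NA)),
    flags = "",
    stringsAsFactors = FALSE
  )
  bad <- !is.na(g$start) & !is.na(g$end) & g$start > g$end
  if (any(bad)) stop("gene with start > end: ", g$id[which(bad)[1]])
  if (any(nchar(g$sequence) == 0)) stop("empty sequence: ",
                                        g$id[nchar(g$sequence) == 0][1])
  class(g) <- c("gc_genes", "data.frame")
  g
}

.empty_genes <- function() {
  g <- data.frame(id = character(), sequence = character(),
                  is_complete = logical(), origin = character(),
                  contig = character(), start = integer(), end = integer(),
                  strand = character(), flags = character(),
                  stringsAsFactors = FALSE)
  class(g) <- c("gc_genes", "data.frame")
  g
}

#' Write genes to FASTA with Prodigal-style headers
#'
#' Inverse of [read_genes()]: completeness is encoded as `partial=00`
#' (complete) or `partial=10` (incomplete).
#'
#' @param genes A `gc_genes` data frame.
#' @param path Output FASTA path.
#' @export
write_genes <- function(genes, path) {
  hdr <- sprintf("%s # %s # %s # %s # ID=%s;partial=%s%s%s",
                 genes$id,
                 ifelse(is.na(genes$start), 1L, genes$start),
                 ifelse(is.na(genes$end), nchar(genes$sequence) * 3L, genes$end),
                 ifelse(is.na(genes$strand) | genes$strand == "+", "1", "-1"),
                 genes$id,
                 ifelse(genes$is_complete, "00", "10"),
                 ifelse(is.na(genes$origin), "", paste0(";origin=", genes$origin)),
                 ifelse(is.na(genes$contig), "", paste0(";contig=", genes$contig)))
  x <- Biostrings::AAStringSet(genes$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read cluster membership (representative to member pairs)
#'
#' The file is the two-column MMseqs2 cluster TSV: representative, member,
#' one pair per line, the representative also listed as its own member.
#'
#' @param path Path to a two-column TSV (no header).
#' @return A `gc_clusters` object (see [gene_clusters()]).
#' @export
read_cluster_membership <- function(path) {
  tb <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  if (ncol(tb) != 2)
    stop("cluster membership must have 2 columns, found ", ncol(tb))
  gene_clusters(data.frame(representative = tb[[1]], member = tb[[2]],
                           stringsAsFactors = FALSE))
}

#' Write cluster membership as a two-column TSV
#'
#' @param clusters A `gc_clusters` object.
#' @param path Output path.
#' @export
write_cluster_membership <- function(clusters, path) {
  reps <- rep(clusters$representative, lengths(clusters$members))
  data.table::fwrite(data.table::data.table(rep = reps,
                                            member = unlist(clusters$members)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a typed hit table
#'
#' Parses one of the three homology-evidence tiers. Rows violating the type
#' invariants (negative e-values, zero aligned columns, coordinates out of
#' order, coverages outside `[0,1]`) are dropped and counted in a message.
#' E-values reported as 0 are clamped to `1e-308` so log transforms stay
#' defined; probabilities given as percents (values > 1) are divided by 100.
#'
#' @param path Path to a TSV with a header row.
#' @param kind One of `"domain"`, `"homolog"`, `"profile"`.
#' @return A `data.frame` with the canonical columns for the kind.
#' @export
read_hits <- function(path, kind = c("domain", "homolog", "profile")) {
  kind <- match.arg(kind)
  cols <- .hit_columns[[kind]]
  tb <- data.table::fread(path, header = TRUE, sep = "\t")
  if (ncol(tb) != length(cols))
    stop("'", kind, "' table must have ", length(cols), " columns, found ",
         ncol(tb), " in ", path)
  data.table::setnames(tb, cols)
  df <- data.table::setDF(tb)
  validate_hits(df, kind)
}

#' Enforce hit-table invariants on an in-memory table
#'
#' @param df Data frame with the canonical columns of the kind.
#' @param kind One of `"domain"`, `"homolog"`, `"profile"`.
#' @return The filtered data frame.
#' @export
validate_hits <- function(df, kind = c("domain", "homolog", "profile")) {
  kind <- match.arg(kind)
  cols <- .hit_columns[[kind]]
  stopifnot(all(cols %in% names(df)))
  n0 <- nrow(df)
  if (kind == "domain") {
    df$terminal_variant[!df$terminal_variant %in% c("N", "C", "M")] <- "none"
    ok <- df$env_start <= df$env_end & df$i_evalue >= 0 &
      df$coverage >= 0 & df$coverage <= 1
  } else if (kind == "homolog") {
    df$evalue[df$evalue == 0] <- 1e-308
    df$target_is_duf <- as.logical(df$target_is_duf)
    ok <- df$evalue > 0 & df$query_cov >= 0 & df$query_cov <= 1 &
      df$target_cov >= 0 & df$target_cov <= 1
  } else {
    df$probability <- ifelse(df$probability > 1, df$probability / 100,
                             df$probability)
    ok <- df$probability >= 0 & df$probability <= 1 & df$aligned_cols >= 1 &
      df$query_cov >= 0 & df$query_cov <= 1 &
      df$target_cov >= 0 & df$target_cov <= 1
  }
  ok[is.na(ok)] <- FALSE
  if (any(!ok))
    message("read_hits(", kind, "): dropped ", sum(!ok), " of ", n0,
            " rows violating invariants")
  df[ok, , drop = FALSE]
}

#' Write a typed hit table
#'
#' @param df Data frame with the canonical columns.
#' @param path Output TSV path.
#' @export
write_hits <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
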
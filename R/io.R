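#' Read genotype and metadata tables
#'
#' Reads a diploid microsatellite genotype table together with a sample
#' metadata table and returns a validated [kin_samples] container.
#'
#' Two genotype dialects are supported:
#' \describe{
#'   \item{\code{"csv"}}{a CSV/TSV with a \code{sample_id} column and either
#'     two columns per locus (\code{<locus>_1}, \code{<locus>_2}) or one
#'     packed column per locus of the form \code{"a1/a2"} (detected
#'     automatically).}
#'   \item{\code{"genepop"}}{a standard GenePop file with 2- or 3-digit
#'     allele codes; \code{0} (i.e. \code{"0000"} / \code{"000000"}) marks a
#'     missing locus.}
#' }
#' Allele cells that cannot be parsed as integers, or that match a missing
#' code, are set to missing with a warning. A locus with only one of its two
#' alleles present is treated as wholly missing at that locus.
#'
#' @param genotype_path path to the genotype table.
#' @param metadata_path optional path to a CSV of per-sample metadata (see
#'   [kin_samples] for recognised columns); if \code{NULL} an empty metadata
#'   frame is created.
#' @param format \code{"csv"} or \code{"genepop"}.
#' @param missing_codes character vector of cell values treated as missing.
#' @param sep field separator for the CSV dialect (\code{","} default).
#' @param date_window passed to [kin_samples].
#' @return A [kin_samples] object. Hard errors: duplicated sample ids, or
#'   genotype/metadata id mismatch (offending ids are listed).
#' @seealso [write_samples]
#' @export
read_samples <- function(genotype_path, metadata_path = NULL,
                         format = c("csv", "genepop"),
                         missing_codes = c("0", "", "NA", "?"),
                         sep = ",",
                         date_window = c(as.Date("1900-01-01"), Sys.Date())) {
  format <- match.arg(format)
  if (!file.exists(genotype_path)) stop("genotype file not found: ", genotype_path)
  gt <- if (format == "csv") {
    .read_geno_csv(genotype_path, missing_codes, sep)
  } else {
    .read_genepop(genotype_path)
  }

  meta <- data.frame(sample_id = gt$ids, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
    md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
    if (!"sample_id" %in% names(md)) stop("metadata must contain sample_id")
    md$sample_id <- as.character(md$sample_id)
    only_g <- setdiff(gt$ids, md$sample_id)
    only_m <- setdiff(md$sample_id, gt$ids)
    if (length(only_g) || length(only_m)) {
      stop("genotype/metadata sample_id mismatch; only in genotypes: ",
           paste(only_g, collapse = ", "), "; only in metadata: ",
           paste(only_m, collapse = ", "))
    }
    meta <- md[match(gt$ids, md$sample_id), , drop = FALSE]
  }
  kin_samples(gt$geno, meta, loci = gt$loci, date_window = date_window)
}

.read_geno_csv <- function(path, missing_codes, sep) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, sep = sep,
                        colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("genotype table must contain sample_id")
  ids <- df$sample_id
  cols <- setdiff(names(df), "sample_id")
  two_col <- grepl("_[12]$", cols)
  if (all(two_col)) {
    loci <- unique(sub("_[12]$", "", cols))
    need <- c(paste0(loci, "_1"), paste0(loci, "_2"))
    miss <- setdiff(need, cols)
    if (length(miss)) stop("locus columns incomplete: ", paste(miss, collapse = ", "))
    a1 <- as.matrix(df[, paste0(loci, "_1"), drop = FALSE])
    a2 <- as.matrix(df[, paste0(loci, "_2"), drop = FALSE])
  } else {
    # packed dialect: one "a1/a2" column per locus
    loci <- cols
    packed <- as.matrix(df[, cols, drop = FALSE])
    sp <- strsplit(as.vector(packed), "/", fixed = TRUE)
    a1 <- matrix(vapply(sp, function(x) if (length(x) >= 1) x[1] else NA_character_,
                        character(1)), nrow = nrow(df))
    a2 <- matrix(vapply(sp, function(x) if (length(x) >= 2) x[2] else NA_character_,
                        character(1)), nrow = nrow(df))
  }
  geno <- matrix(NA_integer_, nrow(df), 2 * length(loci))
  n_bad <- 0L
  for (l in seq_along(loci)) {
    for (k in 1:2) {
      v <- if (k == 1) a1[, l] else a2[, l]
      v[v %in% missing_codes] <- NA
      vi <- suppressWarnings(as.integer(v))
      bad <- !is.na(v) & is.na(vi)
      n_bad <- n_bad + sum(bad)
      geno[, 2 * l - 2 + k] <- vi
    }
  }
  if (n_bad > 0)
    warning(sprintf("%d unparseable allele cell(s) set to missing", n_bad))
  list(geno = geno, ids = ids, loci = loci)
}

# minimal GenePop reader: title line, locus names (one per line or
# comma-separated), "Pop" blocks of "id , a1a2 a1a2 ..." rows
.read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a valid GenePop file: ", path)
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no Pop line found in GenePop file")
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  data_lines <- body[-seq_len(pop_idx[1])]
  data_lines <- data_lines[!grepl("^\\s*pop\\s*$", data_lines, ignore.case = TRUE)]
  ids <- character(length(data_lines))
  geno <- matrix(NA_integer_, length(data_lines), 2 * length(loci))
  for (i in seq_along(data_lines)) {
    parts <- strsplit(data_lines[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop row: ", data_lines[i])
    ids[i] <- trimws(parts[1])
    al <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(al) != length(loci))
      stop("GenePop row has ", length(al), " loci, expected ", length(loci),
           " (sample ", ids[i], ")")
    w <- nchar(al[1]) / 2
    a1 <- as.integer(substr(al, 1, w))
    a2 <- as.integer(substr(al, w + 1, 2 * w))
    a1[a1 == 0] <- NA; a2[a2 == 0] <- NA
    geno[i, seq(1, 2 * length(loci), 2)] <- a1
    geno[i, seq(2, 2 * length(loci), 2)] <- a2
  }
  list(geno = geno, ids = ids, loci = loci)
}

#' Write genotype and metadata tables
#'
#' Writes the canonical CSV dialect (\code{sample_id} plus
#' \code{<locus>_1}/\code{<locus>_2} columns, \code{0} for missing) and,
#' optionally, the metadata CSV. \code{read_samples(write_samples(x))}
#' round-trips cell-for-cell.
#'
#' @param x a [kin_samples] object.
#' @param genotype_path output path for the genotype CSV.
#' @param metadata_path optional output path for the metadata CSV.
#' @param format \code{"csv"} (canonical) or \code{"genepop"}.
#' @return \code{x}, invisibly.
#' @export
write_samples <- function(x, genotype_path, metadata_path = NULL,
                          format = c("csv", "genepop")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "kin_samples"))
  if (format == "csv") {
    g <- x$geno
    g[is.na(g)] <- 0L
    df <- data.frame(sample_id = x$meta$sample_id, g, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, genotype_path, row.names = FALSE, quote = FALSE)
  } else {
    width <- if (max(x$geno, na.rm = TRUE) > 99) 3L else 2L
    fmt <- paste0("%0", width, "d%0", width, "d")
    lines <- c("kinlod export", x$loci, "Pop")
    for (i in seq_len(nrow(x$geno))) {
      a <- x$geno[i, ]
      a[is.na(a)] <- 0L
      al <- sprintf(fmt, a[seq(1, length(a), 2)], a[seq(2, length(a), 2)])
      lines <- c(lines, paste0(x$meta$sample_id[i], " , ", paste(al, collapse = " ")))
    }
    writeLines(lines, genotype_path)
  }
  if (!is.null(metadata_path)) {
    md <- x$meta
    md$date <- format(md$date)
    utils::write.csv(md, metadata_path, row.names = FALSE, na = "")
  }
  invisible(x)
}
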
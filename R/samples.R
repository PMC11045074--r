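#' Construct a multilocus sample table
#'
#' Bundles a genotype matrix with per-sample metadata into the container the
#' rest of the package operates on. Genotypes are diploid microsatellite
#' calls: two integer allele labels per locus, \code{NA} for missing.
#' The allele pair at each locus is stored unordered (sorted), so equality
#' of genotypes does not depend on input allele order.
#'
#' @param geno integer matrix with \code{n} rows and \code{2 * n_loci}
#'   columns (two adjacent columns per locus); \code{NA} marks a missing
#'   allele. If one allele of a pair is missing the whole locus is treated
#'   as missing.
#' @param meta data frame with one row per sample. Must contain
#'   \code{sample_id}; recognised optional columns are \code{sex}
#'   (\code{"F"}, \code{"M"} or \code{NA}), \code{haplotype} (maternally
#'   inherited mtDNA label), \code{length_m} (visually estimated body
#'   length, metres), \code{date} (\code{Date} or ISO-8601 string),
#'   \code{lat}, \code{lon} (decimal degrees, longitude stored in
#'   (-180, 180]), \code{vessel} and \code{field_obs} (free-text flag such
#'   as \code{"MC:<sample_id>"} linking a field-observed mother-calf pair).
#'   Missing columns are filled with \code{NA}.
#' @param loci character vector of locus names (defaults derived from
#'   \code{geno} column names, else \code{L1, L2, ...}).
#' @param date_window two dates; sampling dates outside this window are a
#'   validation error. Default 1900-01-01 to today.
#' @return An object of class \code{kin_samples}: a list with elements
#'   \code{geno}, \code{meta} and \code{loci}.
#' @export
kin_samples <- function(geno, meta, loci = NULL,
                        date_window = c(as.Date("1900-01-01"), Sys.Date())) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) %% 2 != 0) stop("genotype matrix must have two columns per locus")
  n_loci <- ncol(geno) / 2
  if (is.null(loci)) {
    cn <- colnames(geno)
    loci <- if (!is.null(cn)) unique(sub("_[12]$", "", cn)) else paste0("L", seq_len(n_loci))
    if (length(loci) != n_loci) loci <- paste0("L", seq_len(n_loci))
  }
  if (length(loci) != n_loci) stop("length(loci) does not match genotype columns")
  loci <- unname(loci)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) stop("meta must contain a sample_id column")
  if (nrow(meta) != nrow(geno)) stop("geno and meta row counts differ")
  meta$sample_id <- as.character(meta$sample_id)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup)) stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))

  defaults <- list(sex = NA_character_, haplotype = NA_character_,
                   length_m = NA_real_, date = as.Date(NA), lat = NA_real_,
                   lon = NA_real_, vessel = NA_character_, field_obs = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(meta)) meta[[nm]] <- defaults[[nm]]
  }
  meta$date <- as.Date(meta$date)
  meta$sex <- toupper(as.character(meta$sex))
  meta$sex[!meta$sex %in% c("F", "M")] <- NA_character_
  meta$haplotype <- as.character(meta$haplotype)
  meta$haplotype[!nzchar(meta$haplotype) | is.na(meta$haplotype)] <- NA_character_
  meta$length_m <- as.numeric(meta$length_m)
  meta$lat <- as.numeric(meta$lat)
  meta$lon <- .wrap_lon(as.numeric(meta$lon))

  bad_lat <- which(!is.na(meta$lat) & abs(meta$lat) > 90)
  if (length(bad_lat)) stop("latitude out of [-90, 90] for: ",
                            paste(meta$sample_id[bad_lat], collapse = ", "))
  bad_date <- which(!is.na(meta$date) &
                      (meta$date < date_window[1] | meta$date > date_window[2]))
  if (length(bad_date)) stop("sampling date outside plausible window for: ",
                             paste(meta$sample_id[bad_date], collapse = ", "))
  if (!is.na(meta$length_m[1]) || any(!is.na(meta$length_m))) {
    bad_len <- which(!is.na(meta$length_m) & meta$length_m <= 0)
    if (length(bad_len)) stop("non-positive body length for: ",
                              paste(meta$sample_id[bad_len], collapse = ", "))
  }

  # canonicalise each allele pair: sorted, and half-missing pairs -> missing
  for (l in seq_len(n_loci)) {
    c1 <- 2 * l - 1; c2 <- 2 * l
    a <- geno[, c1]; b <- geno[, c2]
    half <- xor(is.na(a), is.na(b))
    a[half] <- NA; b[half] <- NA
    lo <- pmin(a, b); hi <- pmax(a, b)
    geno[, c1] <- lo; geno[, c2] <- hi
  }
  colnames(geno) <- paste0(rep(loci, each = 2), "_", rep(1:2, n_loci))
  rownames(geno) <- meta$sample_id
  rownames(meta) <- NULL

  structure(list(geno = geno, meta = meta, loci = loci), class = "kin_samples")
}

#' @export
print.kin_samples <- function(x, ...) {
  n <- nrow(x$geno)
  typed <- colMeans(!is.na(x$geno[, seq(1, ncol(x$geno), by = 2), drop = FALSE]))
  cat(sprintf("kin_samples: %d samples, %d microsatellite loci\n", n, length(x$loci)))
  cat(sprintf("  fully typed samples: %d; mean per-locus call rate %.3f\n",
              sum(rowSums(is.na(x$geno)) == 0), mean(typed)))
  sx <- table(factor(x$meta$sex, levels = c("F", "M")), useNA = "ifany")
  cat("  sex: ", paste(names(sx), sx, sep = "=", collapse = " "), "\n", sep = "")
  if (any(!is.na(x$meta$date)))
    cat("  dates: ", format(min(x$meta$date, na.rm = TRUE)), " to ",
        format(max(x$meta$date, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Number of samples in a \code{kin_samples} object
#' @param x a \code{kin_samples} object.
#' @return integer sample count.
#' @export
n_samples <- function(x) nrow(x$geno)

# subset samples by row index, keeping the container valid
.subset_samples <- function(x, idx) {
  structure(list(geno = x$geno[idx, , drop = FALSE],
                 meta = x$meta[idx, , drop = FALSE],
                 loci = x$loci),
            class = "kin_samples")
}

# wrap longitudes into (-180, 180]
.wrap_lon <- function(lon) {
  w <- ((lon + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}
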
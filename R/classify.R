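#' Select close-kin dyads above a LOD cut-off
#'
#' Filters scored pairs to those whose LOD under the scored hypothesis
#' exceeds the cut-off, sorts them by descending LOD, attaches both
#' members' metadata (sex, mtDNA haplotype, body length, sampling date and
#' position, vessel), flags field-confirmed mother-calf pairs, computes
#' elapsed days between the two sampling events, and annotates maternal
#' consistency via [annotate_maternal()]. Dyads classified FS by maximum
#' likelihood are flagged low-confidence: with markers of this
#' informativeness the evidence for full sibship over PO/HS is weak.
#'
#' @param pairs a \code{kin_pairs} data frame from [predict.kin_model()].
#' @param samples the [kin_samples] the pairs were scored on.
#' @param scored hypothesis whose LOD is thresholded (\code{"PO"} default).
#' @param cutoff LOD cut-off (natural-log units); pairs strictly above are
#'   kept.
#' @return A data frame of class \code{kin_dyads}; one row per dyad.
#' @export
select_dyads <- function(pairs, samples, scored = "PO", cutoff = 6) {
  stopifnot(inherits(samples, "kin_samples"))
  sc <- paste0("lod_", scored)
  v <- pairs[[sc]]
  keep <- which(!is.na(v) & v > cutoff)
  d <- pairs[keep, , drop = FALSE]
  d <- d[order(-d[[sc]]), , drop = FALSE]
  m <- samples$meta
  i <- match(d$id_i, m$sample_id)
  j <- match(d$id_j, m$sample_id)
  if (anyNA(i) || anyNA(j)) stop("pair ids not found in samples")
  d$cutoff_passed <- rep(cutoff, nrow(d))
  d$sex_i <- m$sex[i];        d$sex_j <- m$sex[j]
  d$hap_i <- m$haplotype[i];  d$hap_j <- m$haplotype[j]
  d$length_i <- m$length_m[i]; d$length_j <- m$length_m[j]
  d$date_i <- m$date[i];      d$date_j <- m$date[j]
  d$lat_i <- m$lat[i];        d$lat_j <- m$lat[j]
  d$lon_i <- m$lon[i];        d$lon_j <- m$lon[j]
  d$vessel_i <- m$vessel[i];  d$vessel_j <- m$vessel[j]
  d$field_confirmed <- .is_field_mc(m, i, j)
  d$elapsed_days <- as.integer(abs(as.numeric(d$date_j - d$date_i)))
  d$low_confidence <- d$ml_category == "FS"
  rownames(d) <- NULL
  d <- annotate_maternal(d)
  class(d) <- c("kin_dyads", "data.frame")
  d
}

# TRUE where records i and j are linked by a field mother-calf observation
# (field_obs of the form "MC:<sample_id>")
.is_field_mc <- function(meta, i, j) {
  fi <- meta$field_obs[i]; fj <- meta$field_obs[j]
  idi <- meta$sample_id[i]; idj <- meta$sample_id[j]
  (!is.na(fi) & fi == paste0("MC:", idj)) |
    (!is.na(fj) & fj == paste0("MC:", idi))
}

#' Annotate dyads with maternal (mtDNA/sex) consistency
#'
#' mtDNA haplotypes are maternally inherited, so a mother and her offspring
#' must share a haplotype. For each dyad with both haplotypes known and
#' equal: a male-female pair is labelled \code{"MS"} (consistent with
#' mother-son), a female-female pair \code{"MD"} (mother-daughter), and a
#' male-male pair \code{"none"} (two males cannot be mother and offspring;
#' no maternal label applies). Dyads with differing known haplotypes get
#' \code{"none"}; any unknown haplotype or sex gives \code{"n/a"}. The
#' label never designates which member is the parent. When a dyad is
#' labelled MS/MD and both body lengths are known, the larger individual is
#' flagged as the presumed mother (for MS only if the larger one is the
#' female) — a consistency note that never changes the label.
#'
#' @param dyads a \code{kin_dyads} data frame (or any data frame with
#'   \code{sex_i}, \code{sex_j}, \code{hap_i}, \code{hap_j},
#'   \code{length_i}, \code{length_j}, \code{id_i}, \code{id_j}).
#' @return The input with columns \code{maternal} and
#'   \code{presumed_mother} added/overwritten.
#' @export
annotate_maternal <- function(dyads) {
  n <- nrow(dyads)
  maternal <- rep("n/a", n)
  mother <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    sx <- c(dyads$sex_i[r], dyads$sex_j[r])
    hp <- c(dyads$hap_i[r], dyads$hap_j[r])
    if (anyNA(hp) || anyNA(sx)) { maternal[r] <- "n/a"; next }
    if (hp[1] != hp[2]) { maternal[r] <- "none"; next }
    lab <- if (setequal(sx, c("M", "F"))) "MS"
           else if (all(sx == "F")) "MD"
           else "none"
    maternal[r] <- lab
    if (lab %in% c("MS", "MD")) {
      len <- c(dyads$length_i[r], dyads$length_j[r])
      if (!anyNA(len) && len[1] != len[2]) {
        big <- which.max(len)
        if (lab == "MD" || sx[big] == "F")
          mother[r] <- c(dyads$id_i[r], dyads$id_j[r])[big]
      }
    }
  }
  dyads$maternal <- maternal
  dyads$presumed_mother <- mother
  dyads
}

#' Assemble triads from overlapping dyads
#'
#' Individuals occurring in more than one dyad link dyads into larger
#' connected groups. Connected components of the dyad graph with three or
#' more members are returned as triads; components of exactly two members
#' remain plain dyads and are not reported here.
#'
#' @param dyads a \code{kin_dyads} data frame.
#' @return A list of class \code{kin_triads}; each element has
#'   \code{members}, \code{shared} (members in more than one dyad) and
#'   \code{edges} (the member dyads with their LODs).
#' @export
build_triads <- function(dyads) {
  out <- list()
  if (nrow(dyads)) {
    g <- igraph::graph_from_data_frame(
      dyads[, c("id_i", "id_j")], directed = FALSE)
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == cid]
      if (length(members) < 3) next
      ed <- dyads[dyads$id_i %in% members & dyads$id_j %in% members, ,
                  drop = FALSE]
      deg <- table(c(ed$id_i, ed$id_j))
      out[[length(out) + 1L]] <- list(
        members = members,
        shared = names(deg)[deg >= 2],
        edges = as.data.frame(ed[, intersect(c("id_i", "id_j", "lod_PO",
                                               "lod_HS", "ml_category"),
                                             names(ed))]))
    }
  }
  structure(out, class = "kin_triads")
}

#' @export
print.kin_triads <- function(x, ...) {
  cat(sprintf("kin_triads: %d group(s) of >= 3 linked individuals\n", length(x)))
  for (t in x)
    cat("  {", paste(t$members, collapse = ", "), "} via ",
        paste(t$shared, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Elapsed time between the sampling events of each dyad
#'
#' Reports, per dyad, the earlier and later sampling dates and the elapsed
#' time in whole years (calendar-day difference divided by 365.25, floored),
#' so that two samples taken in the same austral season report 0 years.
#' Dyads with a missing date are excluded with a warning.
#'
#' @param dyads a \code{kin_dyads} data frame.
#' @return Data frame: \code{id_i}, \code{id_j}, \code{first_date},
#'   \code{second_date}, \code{elapsed_days}, \code{elapsed_years}; the
#'   maximum elapsed years is attached as attribute \code{"max_years"}.
#' @export
elapsed_time_summary <- function(dyads) {
  miss <- is.na(dyads$date_i) | is.na(dyads$date_j)
  if (any(miss)) {
    warning(sum(miss), " dyad(s) excluded for missing sampling date")
    dyads <- dyads[!miss, , drop = FALSE]
  }
  first <- pmin(dyads$date_i, dyads$date_j)
  second <- pmax(dyads$date_i, dyads$date_j)
  days <- as.integer(as.numeric(second - first))
  out <- data.frame(id_i = dyads$id_i, id_j = dyads$id_j,
                    first_date = first, second_date = second,
                    elapsed_days = days,
                    elapsed_years = as.integer(floor(days / 365.25)),
                    stringsAsFactors = FALSE)
  attr(out, "max_years") <- if (nrow(out)) max(out$elapsed_years) else NA_integer_
  out
}
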
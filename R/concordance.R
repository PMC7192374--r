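#' Cross-classifier / cross-condition concordance table
#'
#' Compares two call sets over their common samples. Under the default
#' \code{"primary"} rule a sample matches when both primary subtypes are
#' non-UNS and equal — concordance is established on the highest-correlation
#' subtype only. The \code{"lenient"} rule additionally counts a match when
#' either call's dual list contains the other call's primary subtype. UNS
#' never matches anything, including another UNS.
#'
#' The per-subtype breakdown groups samples by the reference (\code{calls_a})
#' primary subtype, so it is reference-dependent; the overall match count is
#' symmetric in the two arguments.
#'
#' @param calls_a reference \code{subtype_calls} table.
#' @param calls_b comparison \code{subtype_calls} table.
#' @param match_rule \code{"primary"} (default) or \code{"lenient"}.
#' @return object of class \code{concordance_report}: \code{n_samples},
#'   \code{n_matched}, \code{match_fraction}, \code{per_subtype} data.frame
#'   (n_reference, n_matched, fraction by reference subtype),
#'   \code{mismatches}, and dual/UNS counts for both call sets.
#' @export
concordance_table <- function(calls_a, calls_b,
                              match_rule = c("primary", "lenient")) {
  match_rule <- match.arg(match_rule)
  calls_a <- subtype_calls(calls_a)
  calls_b <- subtype_calls(calls_b)
  common <- intersect(calls_a$sample_id, calls_b$sample_id)
  if (!length(common))
    stop("the two call sets share no samples", call. = FALSE)
  if (length(common) < nrow(calls_a) || length(common) < nrow(calls_b))
    warning("call sets differ in samples; using the ", length(common),
            " common ones", call. = FALSE)
  a <- calls_a[match(common, calls_a$sample_id), ]
  b <- calls_b[match(common, calls_b$sample_id), ]
  matched <- mapply(function(sa, pa, da, sb, pb, db) {
    if (sa == "unstable" || sb == "unstable") return(FALSE)
    if (pa == pb) return(TRUE)
    if (match_rule == "lenient")
      return(pb %in% parse_duals(da)$subtype ||
             pa %in% parse_duals(db)$subtype)
    FALSE
  }, a$status, a$primary_subtype, a$dual_subtypes,
     b$status, b$primary_subtype, b$dual_subtypes)
  ref_sub <- a$primary_subtype[a$status != "unstable"]
  per <- do.call(rbind, lapply(sort(unique(ref_sub)), function(s) {
    idx <- which(a$primary_subtype == s & a$status != "unstable")
    data.frame(reference_subtype = s, n_reference = length(idx),
               n_matched = sum(matched[idx]),
               fraction = sum(matched[idx]) / length(idx))
  }))
  if (is.null(per))
    per <- data.frame(reference_subtype = character(),
                      n_reference = integer(), n_matched = integer(),
                      fraction = numeric())
  mm <- data.frame(
    sample_id = common[!matched],
    call_a = ifelse(a$status == "unstable", "UNS",
                    a$primary_subtype)[!matched],
    call_b = ifelse(b$status == "unstable", "UNS",
                    b$primary_subtype)[!matched])
  structure(list(n_samples = length(common),
                 n_matched = sum(matched),
                 match_fraction = sum(matched) / length(common),
                 per_subtype = per,
                 mismatches = mm,
                 matched_samples = sort(common[matched]),
                 dual_count_a = sum(a$status == "dual"),
                 dual_count_b = sum(b$status == "dual"),
                 uns_count_a = sum(a$status == "unstable"),
                 uns_count_b = sum(b$status == "unstable"),
                 match_rule = match_rule),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d samples concordant (%.0f%%), rule = %s\n",
              x$n_matched, x$n_samples, 100 * x$match_fraction,
              x$match_rule))
  if (nrow(x$per_subtype)) {
    cat("per reference subtype:\n")
    print(x$per_subtype, row.names = FALSE)
  }
  invisible(x)
}

#' Identify samples with a stable subtype across conditions
#'
#' A sample is stable when its primary subtype is identical and non-UNS in
#' every condition in which it appears. Conditions missing a sample (e.g. a
#' cell line not represented in a dataset) are skipped for that sample
#' rather than breaking its stability; a sample must appear in at least one
#' condition to be evaluated.
#'
#' @param call_sets named list (condition label -> \code{subtype_calls}) of
#'   at least two conditions.
#' @return object of class \code{stability_result}:
#'   \code{sample_ids_stable} (sorted), \code{n_conditions}, and a
#'   per-sample \code{pattern} data.frame of calls by condition (NA where
#'   absent, "UNS" for unstable).
#' @export
stable_set <- function(call_sets) {
  if (!is.list(call_sets) || length(call_sets) < 2)
    stop("need at least 2 conditions", call. = FALSE)
  if (is.null(names(call_sets)) || any(!nzchar(names(call_sets))))
    names(call_sets) <- paste0("condition_", seq_along(call_sets))
  call_sets <- lapply(call_sets, subtype_calls)
  samples <- sort(unique(unlist(lapply(call_sets, `[[`, "sample_id"))))
  if (!length(samples))
    stop("no samples in any condition", call. = FALSE)
  pattern <- vapply(call_sets, function(cs) {
    lab <- ifelse(cs$status == "unstable", "UNS", cs$primary_subtype)
    lab[match(samples, cs$sample_id)]
  }, character(length(samples)))
  pattern <- matrix(pattern, nrow = length(samples),
                    dimnames = list(samples, names(call_sets)))
  stable <- apply(pattern, 1, function(p) {
    p <- p[!is.na(p)]
    length(p) > 0 && !any(p == "UNS") && length(unique(p)) == 1
  })
  structure(list(sample_ids_stable = samples[stable],
                 n_conditions = length(call_sets),
                 pattern = as.data.frame(pattern)),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d/%d samples stable across %d conditions\n",
              length(x$sample_ids_stable), nrow(x$pattern), x$n_conditions))
  if (length(x$sample_ids_stable))
    cat("stable:", paste(x$sample_ids_stable, collapse = ", "), "\n")
  invisible(x)
}

#' Audit dual-subtype calls
#'
#' @param calls a \code{subtype_calls} table.
#' @return list: \code{count} of dual calls and a \code{duals} data.frame
#'   (sample, primary subtype, serialized ranked dual list).
#' @export
dual_subtype_audit <- function(calls) {
  calls <- subtype_calls(calls)
  idx <- which(calls$status == "dual")
  list(count = length(idx),
       duals = data.frame(sample_id = calls$sample_id[idx],
                          primary_subtype = calls$primary_subtype[idx],
                          dual_subtypes = calls$dual_subtypes[idx]))
}
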
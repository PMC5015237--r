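# Confusion-matrix construction and the four diagnostic estimators, plus
# ground-truth matching for phantom runs and per-unit clinical rollups.

#' Confusion counts
#'
#' The four crosstab cells: `a` true positives, `b` false positives, `c`
#' false negatives, `d` true negatives.  `d` may be unknown (`NA`), as when
#' only the positive calls of a program are adjudicated; rates whose
#' denominator involves an unknown cell are then undefined.
#'
#' @param a,b,c Non-negative integer counts.
#' @param d Non-negative integer count, or `NA` when not available.
#' @return An object of class `sln_confusion`.
#' @export
confusion_counts <- function(a, b = 0L, c = 0L, d = NA_integer_) {
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("count `%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (length(d) != 1L || (!is.na(d) && d < 0)) {
    stop("count `d` must be a single non-negative number or NA",
         call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d)), class = "sln_confusion")
}

#' @export
print.sln_confusion <- function(x, ...) {
  cat(sprintf("<sln_confusion> a=%g b=%g c=%g d=%s\n", x$a, x$b, x$c,
              ifelse(is.na(x$d), "unknown", format(x$d))))
  invisible(x)
}

#' Diagnostic rates from a crosstab
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, false-positive rate
#' `b/(b+d)` and false-negative rate `c/(a+c)`.  A rate whose denominator is
#' zero or involves an unknown `d` is returned as `NA` ("undefined"), never
#' as 0.  By construction sensitivity + FN rate = 1 and specificity +
#' FP rate = 1 whenever defined.
#'
#' @param cc A [confusion_counts()].
#' @return Named list with `sensitivity`, `specificity`, `fp_rate`,
#'   `fn_rate` (each a proportion in `[0, 1]` or `NA`).
#' @export
rates <- function(cc) {
  stopifnot(inherits(cc, "sln_confusion"))
  pos <- cc$a + cc$c
  neg <- if (is.na(cc$d)) NA_real_ else cc$b + cc$d
  sens <- if (pos > 0) cc$a / pos else NA_real_
  spec <- if (!is.na(neg) && neg > 0) cc$d / neg else NA_real_
  list(sensitivity = sens,
       specificity = spec,
       fp_rate = if (!is.na(neg) && neg > 0) cc$b / neg else NA_real_,
       fn_rate = if (pos > 0) cc$c / pos else NA_real_)
}

#' Crosstab from program and corrected lists
#'
#' Compares the program's true/false partition of findings with the
#' expert-corrected partition over the same labels: `a` = true in both,
#' `b` = program-true but corrected-false (false positives), `c` =
#' program-false but corrected-true (false negatives), `d` = false in both.
#'
#' @param program,corrected Each a list with elements `true` and `false`
#'   holding label vectors, or [rank_findings()] results (labels are taken
#'   from the frames).
#' @return A [confusion_counts()] with known `d`.
#' @export
crosstab_from_lists <- function(program, corrected) {
  labs <- function(x) {
    if (inherits(x, "sln_ranked")) {
      list(true = x$true$label, false = x$false$label)
    } else {
      lapply(x[c("true", "false")], function(e) {
        if (is.data.frame(e)) e$label else e
      })
    }
  }
  p <- labs(program); q <- labs(corrected)
  all_p <- c(p$true, p$false); all_q <- c(q$true, q$false)
  if (anyDuplicated(all_p) || anyDuplicated(all_q)) {
    stop("a label appears on both lists of one partition", call. = FALSE)
  }
  miss <- union(setdiff(all_p, all_q), setdiff(all_q, all_p))
  if (length(miss)) {
    stop(sprintf("label sets differ between partitions: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  confusion_counts(a = length(intersect(p$true, q$true)),
                   b = length(intersect(p$true, q$false)),
                   c = length(intersect(p$false, q$true)),
                   d = length(intersect(p$false, q$false)))
}

#' Correction rate
#'
#' Fraction of findings moved by the experts in either direction:
#' `(b + c) / (a + b + c + d)`.
#'
#' @param cc A [confusion_counts()] with known `d`.
#' @return Proportion in `[0, 1]`.
#' @export
correction_rate <- function(cc) {
  stopifnot(inherits(cc, "sln_confusion"))
  if (is.na(cc$d)) stop("correction rate needs all four cells", call. = FALSE)
  (cc$b + cc$c) / (cc$a + cc$b + cc$c + cc$d)
}

#' Matching specification for phantom evaluation
#'
#' @param max_centroid_distance_mm Maximum centroid distance for a finding
#'   to count as recovering a planted node (default 10).
#' @return A list of class `sln_match_spec`.
#' @export
match_spec <- function(max_centroid_distance_mm = 10) {
  if (max_centroid_distance_mm <= 0) stop("distance must be > 0",
                                          call. = FALSE)
  structure(list(max_centroid_distance_mm = max_centroid_distance_mm,
                 matching = "greedy_by_probability"),
            class = "sln_match_spec")
}

#' Match findings to phantom ground truth
#'
#' Greedy matching of the true findings, in descending probability, to the
#' planted (non-decoy) node positions within the distance bound; each node
#' can absorb at most one finding.  Matched true findings are `a`; unmatched
#' true findings are `b`; unmatched nodes are `c`; false findings not within
#' the bound of any node are `d`.
#'
#' @param ranked An [rank_findings()] result.
#' @param truth A `sln_phantom_truth` (from [generate_phantom()]) or a data
#'   frame with columns `x_mm`, `y_mm`, `z_mm` and logical `is_decoy`.
#' @param spec A [match_spec()].
#' @return A list: `counts` ([confusion_counts()]), `matched` data frame
#'   (`label`, `node`, `distance_mm`), `unmatched_nodes` integer vector.
#' @export
match_to_truth <- function(ranked, truth, spec = match_spec()) {
  stopifnot(inherits(ranked, "sln_ranked"))
  nodes <- if (inherits(truth, "sln_phantom_truth")) truth$nodes else truth
  real <- nodes[!nodes$is_decoy, , drop = FALSE]
  pos <- as.matrix(real[, c("x_mm", "y_mm", "z_mm")])
  taken <- rep(FALSE, nrow(real))
  matched <- list()
  b <- 0L
  truefinds <- ranked$true
  if (nrow(truefinds)) {
    truefinds <- truefinds[order(-truefinds$probability), , drop = FALSE]
  }
  for (r in seq_len(nrow(truefinds))) {
    f <- truefinds[r, ]
    if (nrow(real) == 0L) { b <- b + 1L; next }
    d <- sqrt(colSums((t(pos) - c(f$centroid_x_mm, f$centroid_y_mm,
                                  f$centroid_z_mm))^2))
    d[taken] <- Inf
    j <- which.min(d)
    if (d[j] <= spec$max_centroid_distance_mm) {
      taken[j] <- TRUE
      matched[[length(matched) + 1L]] <-
        data.frame(label = f$label, node = j, distance_mm = d[j])
    } else {
      b <- b + 1L
    }
  }
  # false findings near a node still failed to present it as a candidate;
  # only those away from every node count as true negatives
  d_false <- 0L
  for (r in seq_len(nrow(ranked$false))) {
    f <- ranked$false[r, ]
    near <- FALSE
    if (nrow(real) > 0L) {
      d <- sqrt(colSums((t(pos) - c(f$centroid_x_mm, f$centroid_y_mm,
                                    f$centroid_z_mm))^2))
      near <- any(d <= spec$max_centroid_distance_mm)
    }
    if (!near) d_false <- d_false + 1L
  }
  list(counts = confusion_counts(a = length(matched), b = b,
                                 c = sum(!taken), d = d_false),
       matched = if (length(matched)) do.call(rbind, matched)
       else data.frame(label = integer(), node = integer(),
                       distance_mm = numeric()),
       unmatched_nodes = which(!taken))
}

#' Per-unit clinical rollup
#'
#' Aggregates one diagnostic outcome per unit (patient or groin) into a
#' crosstab with its rates, and separately computes event proportions
#' (e.g. complications) over all units.  The crosstab false-negative rate
#' (`c/(a+c)`, conditioned on truly positive units) and a procedure-failure
#' proportion (events over all units) are distinct quantities and are both
#' returned.
#'
#' @param assignments Data frame with columns `unit` (unique id) and
#'   `outcome` (`"TP"`, `"FP"`, `"FN"`, `"TN"`); optional further logical
#'   event columns (e.g. `complication`).
#' @return A list: `counts` ([confusion_counts()]), `rates`, `n_units`, and
#'   `proportions` (named: each event column's events / total units, plus
#'   `fn_proportion` = FN units / total units).
#' @export
per_unit_rollup <- function(assignments) {
  if (anyDuplicated(assignments$unit)) {
    stop(sprintf("duplicate unit id(s): %s",
                 paste(unique(assignments$unit[duplicated(assignments$unit)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (!all(assignments$outcome %in% c("TP", "FP", "FN", "TN"))) {
    stop("outcomes must be TP/FP/FN/TN", call. = FALSE)
  }
  tab <- table(factor(assignments$outcome,
                      levels = c("TP", "FP", "FN", "TN")))
  cc <- confusion_counts(a = tab[["TP"]], b = tab[["FP"]], c = tab[["FN"]],
                         d = tab[["TN"]])
  n <- nrow(assignments)
  props <- list(fn_proportion = tab[["FN"]] / n)
  extra <- setdiff(names(assignments), c("unit", "outcome"))
  for (e in extra) props[[paste0(e, "_proportion")]] <-
    sum(assignments[[e]]) / n
  list(counts = cc, rates = rates(cc), n_units = n, proportions = props)
}

#' Format rates the way reports print them
#'
#' Percentages to one decimal place, proportions to three decimals;
#' undefined rates print as `"undefined"`.  Full-precision values are kept
#' in the objects themselves; this is presentation only.
#'
#' @param r A [rates()] result (or any named list of proportions).
#' @param percent Names to render as percentages (default sensitivity and
#'   specificity).
#' @return Named character vector.
#' @export
format_rates <- function(r, percent = c("sensitivity", "specificity")) {
  out <- character(0)
  for (nm in names(r)) {
    v <- r[[nm]]
    out[nm] <- if (is.na(v)) {
      "undefined"
    } else if (nm %in% percent) {
      sprintf("%.1f %%", 100 * v)
    } else {
      sprintf("%.3f", v)
    }
  }
  out
}

#' Plain-text crosstab report
#'
#' Renders a crosstab and its rates as a small fixed-width table.
#'
#' @param cc A [confusion_counts()].
#' @param title Heading line.
#' @return Character vector of lines (also printed invisibly usable with
#'   [writeLines()]).
#' @export
render_crosstab <- function(cc, title = "Crosstab") {
  r <- rates(cc)
  fmt <- function(x) ifelse(is.na(x), "-", format(x))
  lines <- c(
    title,
    sprintf("                 %10s %10s %10s", "proven", "disproven", "sum"),
    sprintf("  positive calls %10s %10s %10s", fmt(cc$a), fmt(cc$b),
            fmt(cc$a + cc$b)),
    sprintf("  negative calls %10s %10s %10s", fmt(cc$c), fmt(cc$d),
            fmt(cc$c + cc$d)),
    sprintf("  sum            %10s %10s %10s", fmt(cc$a + cc$c),
            fmt(cc$b + cc$d), fmt(cc$a + cc$b + cc$c + cc$d)),
    "",
    paste0("  sensitivity: ", format_rates(r)[["sensitivity"]]),
    paste0("  specificity: ", format_rates(r)[["specificity"]]),
    paste0("  FP rate:     ", format_rates(r)[["fp_rate"]]),
    paste0("  FN rate:     ", format_rates(r)[["fn_rate"]]))
  lines
}
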
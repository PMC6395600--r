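# Variance inflation factor screening.

#' Variance inflation factor of one or all variables
#'
#' `VIF = 1 / (1 - R^2)` from the least-squares regression of a variable on
#' all other variables in the table. Perfect collinearity returns `Inf`.
#'
#' @param data Data frame (or matrix) of numeric candidate variables only.
#' @param variable Optional single variable name; by default VIFs for every
#'   column are returned.
#' @return Named numeric vector of VIF values (or a single value).
#' @examples
#' d <- data.frame(a = rnorm(50), b = rnorm(50))
#' vif(d)  # both ~1
#' @export
vif <- function(data, variable = NULL) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("all variables must be numeric")
  if (ncol(x) < 2L) stop("need at least 2 variables")
  if (nrow(x) <= ncol(x)) stop("need more rows than variables")
  consts <- apply(x, 2L, stats::sd) == 0
  if (any(consts))
    stop("constant variable(s): ", paste(colnames(x)[consts], collapse = ", "))
  one <- function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (!is.null(variable)) {
    j <- match(variable, colnames(x))
    if (is.na(j)) stop("unknown variable: ", variable)
    return(one(j))
  }
  out <- vapply(seq_len(ncol(x)), one, 0)
  names(out) <- colnames(x)
  out
}

#' Iterative VIF-based variable elimination
#'
#' Repeatedly removes the single variable with the largest VIF above the
#' threshold (ties broken by column order) and recomputes, until every
#' retained variable has VIF <= threshold. With `groups`, screening runs
#' independently within each named variable group (the default mode of the
#' hypothesis pipeline, which screens per-hypothesis variable sets);
#' otherwise all columns are screened together.
#'
#' @param data Data frame of numeric candidate variables.
#' @param threshold Removal threshold (5, the conventional cutoff).
#' @param groups Optional named list of character vectors partitioning (a
#'   subset of) the columns.
#' @return A `vif_report`: `rounds` (list of named VIF vectors, one per
#'   recomputation), `removed` (in removal order), `retained`, `threshold`.
#' @export
vif_filter <- function(data, threshold = 5, groups = NULL) {
  if (!is.null(groups)) {
    reps <- lapply(groups, function(vars) vif_filter(data[vars], threshold))
    return(structure(list(
      rounds = do.call(c, lapply(reps, `[[`, "rounds")),
      removed = unlist(lapply(reps, `[[`, "removed"), use.names = FALSE),
      retained = unlist(lapply(reps, `[[`, "retained"), use.names = FALSE),
      threshold = threshold, groups = reps), class = "vif_report"))
  }
  vars <- colnames(data)
  removed <- character(0)
  rounds <- list()
  repeat {
    if (length(vars) < 2L) {
      if (length(removed)) warning("fewer than 2 variables remain; stopping")
      break
    }
    v <- vif(data[vars])
    rounds[[length(rounds) + 1L]] <- v
    if (max(v) <= threshold) break
    drop <- vars[which.max(v)]  # which.max: first max in column order
    removed <- c(removed, drop)
    vars <- setdiff(vars, drop)
  }
  structure(list(rounds = rounds, removed = removed, retained = vars,
                 threshold = threshold), class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("vif_filter (threshold %g): %d retained, %d removed\n",
              x$threshold, length(x$retained), length(x$removed)))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a VIF report as a long CSV log
#'
#' @param report A [vif_filter()] report.
#' @param path Output CSV path.
#' @return The log data frame, invisibly.
#' @export
write_vif_log <- function(report, path) {
  logs <- do.call(rbind, lapply(seq_along(report$rounds), function(i) {
    v <- report$rounds[[i]]
    data.frame(round = i, variable = names(v), vif = unname(v))
  }))
  logs$action <- ifelse(logs$variable %in% report$removed &
                          logs$vif > report$threshold, "removed", "retained")
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(logs)
}
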
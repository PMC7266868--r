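#' One-way ANOVA decomposition
#'
#' Standard between/within sum-of-squares decomposition; \code{mse} is the
#' within-group mean square, the error estimate Duncan's test needs.
#' All-constant data (zero within-group variance) is an input error.
#'
#' @param values named list of numeric vectors, >= 2 groups with >= 2
#'   values each.
#' @return list with \code{mse}, \code{df_error}, \code{f_stat}, \code{p},
#'   \code{means}, \code{n_per_group}.
#' @export
one_way_anova <- function(values) {
  if (length(values) < 2) dn_input_error("need >= 2 groups")
  sizes <- lengths(values)
  if (any(sizes < 2))
    dn_input_error("every group needs >= 2 values (group %d has %d)",
                   which(sizes < 2)[1], min(sizes))
  n <- sum(sizes); k <- length(values)
  means <- vapply(values, mean, numeric(1))
  grand <- sum(unlist(values)) / n
  sse <- sum(vapply(values, function(v) sum((v - mean(v))^2), numeric(1)))
  ssb <- sum(sizes * (means - grand)^2)
  df_error <- n - k
  if (sse == 0)
    dn_input_error("no within-group variance (all groups constant)")
  mse <- sse / df_error
  f <- (ssb / (k - 1)) / mse
  list(mse = mse, df_error = df_error, f_stat = f,
       p = stats::pf(f, k - 1, df_error, lower.tail = FALSE),
       means = means, n_per_group = sizes)
}

# Duncan's critical range for a span of p ordered means:
# R_p = q(1 - alpha_p, p, df) * sqrt(mse / n_h), alpha_p = 1-(1-alpha)^(p-1)
duncan_range <- function(p, df_error, mse, n_h, alpha) {
  alpha_p <- 1 - (1 - alpha)^(p - 1)
  stats::qtukey(1 - alpha_p, nmeans = p, df = df_error) * sqrt(mse / n_h)
}

#' Duncan's multiple range test with compact letter display
#'
#' Means are ordered descending (ties broken by label). For each span of p
#' consecutive ordered means the critical range uses the studentized-range
#' quantile at Duncan's protection level \eqn{\alpha_p = 1-(1-\alpha)^{p-1}}
#' and the harmonic-mean group size. The step-down rule applies: a range
#' whose extreme difference does not exceed its critical range is declared
#' homogeneous and none of its internal pairs can later be declared
#' different. Letters come from the maximal homogeneous intervals
#' (insert-and-absorb): groups sharing any letter are not significantly
#' different.
#'
#' @param values named list of numeric vectors (group label -> values).
#' @param alpha protection level (default 0.05).
#' @return a \code{dn_duncan}: list with \code{groups} (descending mean
#'   order), \code{means}, \code{n_per_group}, \code{mse},
#'   \code{df_error}, \code{alpha}, \code{letters}, \code{ranges}
#'   (R_p per span), and \code{different} (logical pairwise matrix).
#' @export
duncan_mrt <- function(values, alpha = 0.05) {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    names(values) <- paste0("G", seq_along(values))
  av <- one_way_anova(values)
  ord <- order(-av$means, names(values))
  labels <- names(values)[ord]
  means <- av$means[ord]
  sizes <- av$n_per_group[ord]
  k <- length(means)
  n_h <- k / sum(1 / sizes)
  ranges <- vapply(2:k, duncan_range, numeric(1),
                   df_error = av$df_error, mse = av$mse, n_h = n_h,
                   alpha = alpha)
  names(ranges) <- paste0("R", 2:k)

  # step-down: NA = undecided, FALSE = homogeneous, TRUE = different
  diff_mat <- matrix(NA, k, k, dimnames = list(labels, labels))
  diag(diff_mat) <- FALSE
  mark_homog <- function(i, j) {
    for (a in i:j) for (b in i:j)
      diff_mat[a, b] <<- FALSE
  }
  recurse <- function(i, j) {
    if (j <= i) return(invisible())
    if (isFALSE(diff_mat[i, j])) return(invisible())  # inside homogeneous span
    p <- j - i + 1
    if (means[i] - means[j] > ranges[p - 1]) {
      if (is.na(diff_mat[i, j])) diff_mat[i, j] <<- diff_mat[j, i] <<- TRUE
      recurse(i, j - 1)
      recurse(i + 1, j)
    } else {
      mark_homog(i, j)
    }
  }
  recurse(1, k)
  diff_mat[is.na(diff_mat)] <- TRUE   # unreachable; defensive

  # maximal homogeneous intervals -> letters
  reach <- vapply(seq_len(k), function(i) {
    j <- i
    while (j < k && !any(diff_mat[i:(j + 1L), i:(j + 1L)])) j <- j + 1L
    j
  }, integer(1))
  intervals <- list()
  for (i in seq_len(k)) {
    iv <- c(i, reach[i])
    if (length(intervals) == 0 ||
        reach[i] > intervals[[length(intervals)]][2])
      intervals[[length(intervals) + 1]] <- iv
  }
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  lts <- character(k)
  for (li in seq_along(intervals)) {
    iv <- intervals[[li]]
    lts[iv[1]:iv[2]] <- paste0(lts[iv[1]:iv[2]], letters_pool[li])
  }
  structure(list(groups = labels, means = unname(means),
                 n_per_group = unname(sizes), mse = av$mse,
                 df_error = av$df_error, alpha = alpha,
                 ranges = ranges, letters = lts,
                 different = diff_mat),
            class = "dn_duncan")
}

#' @export
print.dn_duncan <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %d, MSE = %.4g)\n",
              x$alpha, x$df_error, x$mse))
  print(data.frame(group = x$groups, mean = x$means, n = x$n_per_group,
                   letters = x$letters), row.names = FALSE)
  invisible(x)
}

#' Duncan comparisons across the cells of a measurement table
#'
#' Runs [duncan_mrt()] for every measured variable (hormone or trait,
#' i.e. each matrix row) within each slice of the design:
#' \code{"condition-within-day"} compares control vs drought per variety
#' and day; \code{"day-within-condition"} compares days per variety and
#' condition; \code{"all-cells"} compares every condition x day cell per
#' variety. Slices with fewer than 2 groups of >= 2 replicates are skipped
#' with a warning.
#'
#' @param table variables x samples numeric matrix (e.g. a hormone table).
#' @param sheet sample sheet aligned with the table's columns.
#' @param factor slicing scheme (see above).
#' @param alpha protection level.
#' @return list of entries, each with \code{variable}, \code{variety},
#'   \code{slice} and \code{result} (a \code{dn_duncan}).
#' @export
group_compare_table <- function(table, sheet,
                                factor = c("condition-within-day",
                                           "day-within-condition",
                                           "all-cells"),
                                alpha = 0.05) {
  factor <- match.arg(factor)
  sheet <- sheet[match(colnames(table), sheet$sample_id), , drop = FALSE]
  slices <- list()
  for (v in unique(sheet$variety)) {
    sub <- sheet$variety == v
    if (factor == "condition-within-day") {
      for (d in sort(unique(sheet$day[sub & sheet$day > 0])))
        slices[[paste(v, paste0("d", d))]] <-
          list(variety = v, cols = sub & sheet$day == d,
               group = sheet$condition)
    } else if (factor == "day-within-condition") {
      for (cond in unique(sheet$condition[sub]))
        slices[[paste(v, cond)]] <-
          list(variety = v, cols = sub & sheet$condition == cond,
               group = paste0("d", sheet$day))
    } else {
      slices[[v]] <- list(variety = v, cols = sub,
                          group = paste(sheet$condition,
                                        paste0("d", sheet$day)))
    }
  }
  out <- list()
  for (sl_name in names(slices)) {
    sl <- slices[[sl_name]]
    groups <- split(seq_len(ncol(table))[sl$cols], sl$group[sl$cols])
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) {
      warning(sprintf("slice '%s' skipped: fewer than 2 replicated groups",
                      sl_name))
      next
    }
    for (var in rownames(table)) {
      vals <- lapply(groups, function(ix) unname(table[var, ix]))
      res <- tryCatch(duncan_mrt(vals, alpha = alpha),
                      dn_input_error = function(e) {
                        warning(sprintf("%s / %s skipped: %s", sl_name, var,
                                        conditionMessage(e)))
                        NULL
                      })
      if (!is.null(res))
        out[[paste(sl_name, var, sep = " / ")]] <-
          list(variable = var, variety = sl$variety, slice = sl_name,
               result = res)
    }
  }
  out
}
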
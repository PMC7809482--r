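# Rank-based group comparisons and expansion/seeding capacity arithmetic.

#' Mann-Whitney U test
#'
#' Reports `U = min(U_a, U_b)` with midrank ties. The two-sided p-value is
#' exact (from the null U distribution, equivalent to enumerating all
#' label assignments) when `n_a + n_b <= exact_max` and the data are
#' tie-free; otherwise a normal approximation with tie correction and
#' continuity correction is used. The standardized statistic `z` (of
#' `U_a`) is returned alongside; `correct = FALSE` drops the continuity
#' correction (useful for the algebraic identity `H = z^2` against the
#' two-group Kruskal-Wallis test).
#'
#' @param a,b numeric vectors (both nonempty).
#' @param exact_max largest total sample size for the exact branch.
#' @param correct apply the continuity correction in the approximation?
#' @return list with `U`, `p`, `z`, `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1, exact
#' @export
mann_whitney_u <- function(a, b, exact_max = 12, correct = TRUE) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be nonempty", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(na)])
  ua <- ra - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  ties <- any(duplicated(c(a, b)))
  tie_tab <- table(c(a, b))
  tie_term <- sum(tie_tab^3 - tie_tab)
  mu <- na * nb / 2
  sig2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (sig2 > 0) {
    num <- ua - mu
    if (correct && num != 0) num <- num - sign(num) * 0.5
    num / sqrt(sig2)
  } else 0
  if (!ties && n <= exact_max) {
    p <- min(1, 2 * stats::pwilcox(u, na, nb))
    method <- "exact"
  } else {
    p <- if (sig2 > 0) min(1, 2 * stats::pnorm(-abs(z))) else 1
    method <- "normal"
  }
  list(U = u, p = p, z = z, method = method)
}

# long-format group input -> list(values, groups factor)
as_groups <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("group", "value") %in% names(table)))
    list(values = table$value, groups = factor(table$group))
  } else if (is.list(table)) {
    stopifnot(length(table) >= 2, !is.null(names(table)))
    list(values = unlist(table, use.names = FALSE),
         groups = factor(rep(names(table), lengths(table)),
                         levels = names(table)))
  } else stop("groups must be a named list or a (group, value) data.frame",
              call. = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with midranks, p-value from the
#' chi-square distribution on `k - 1` degrees of freedom (delegated to
#' [stats::kruskal.test()]). When every observation is identical the
#' statistic is defined as 0 with p = 1.
#'
#' @param table named list of numeric vectors, or a long-format
#'   data.frame with columns `group` and `value` (>= 2 groups, total
#'   n >= 3).
#' @return list with `H`, `df`, `p`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))$H  # 3.857
#' @export
kruskal_wallis <- function(table) {
  g <- as_groups(table)
  stopifnot(nlevels(g$groups) >= 2, length(g$values) >= 3)
  if (length(unique(g$values)) == 1)
    return(list(H = 0, df = nlevels(g$groups) - 1L, p = 1))
  kt <- stats::kruskal.test(g$values, g$groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons after Kruskal-Wallis
#'
#' For each pair of groups, `z = (mean_rank_i - mean_rank_j) /
#' sqrt((N(N+1)/12 - tie_term) * (1/n_i + 1/n_j))` with
#' `tie_term = sum(t^3 - t) / (12 (N - 1))` over tie groups, two-sided
#' p from the standard normal; the Bonferroni adjustment multiplies by
#' the number of pairs `k (k - 1) / 2`, capped at 1.
#'
#' @param table as in [kruskal_wallis()].
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return data.frame with `group_i`, `group_j`, `z`, `p_raw`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(table, adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  g <- as_groups(table)
  stopifnot(nlevels(g$groups) >= 2, length(g$values) >= 3)
  N <- length(g$values)
  r <- rank(g$values)
  mean_rank <- tapply(r, g$groups, mean)
  n_i <- tabulate(g$groups)
  tie_tab <- table(g$values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lv <- levels(g$groups)
  k <- length(lv)
  m <- k * (k - 1) / 2
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j])
    z <- if (se2 > 0) (mean_rank[[i]] - mean_rank[[j]]) / sqrt(se2) else 0
    p <- 2 * stats::pnorm(-abs(z))
    padj <- if (adjustment == "bonferroni") min(1, m * p) else p
    rows[[length(rows) + 1]] <- data.frame(group_i = lv[i], group_j = lv[j],
                                           z = z, p_raw = p,
                                           p_adjusted = padj)
  }
  do.call(rbind, rows)
}

#' Assay-plate capacity of an expansion batch
#'
#' How many assay plates can be seeded from a batch of source plates:
#' `floor(n_source_plates * yield_per_plate / (wells_per_assay_plate *
#' cells_per_assay_well))` — partial plates are unusable, hence the
#' floor.
#'
#' @param n_source_plates number of expansion plates (non-negative
#'   integer).
#' @param yield_per_plate cells harvested per source plate (may be a
#'   float estimate; > 0).
#' @param wells_per_assay_plate,cells_per_assay_well assay-plate format
#'   (positive).
#' @return object of class `capacity_plan` (list with the inputs and
#'   `n_assay_plates`).
#' @examples
#' assay_capacity(10, 1.18e7, 384, 20000)$n_assay_plates  # 15
#' @export
assay_capacity <- function(n_source_plates, yield_per_plate,
                           wells_per_assay_plate, cells_per_assay_well) {
  if (n_source_plates < 0 || n_source_plates != round(n_source_plates))
    stop("n_source_plates must be a non-negative integer", call. = FALSE)
  if (yield_per_plate <= 0 || wells_per_assay_plate <= 0 ||
      cells_per_assay_well <= 0)
    stop("yields and plate format must be positive", call. = FALSE)
  n <- floor(n_source_plates * yield_per_plate /
               (wells_per_assay_plate * cells_per_assay_well))
  structure(list(n_source_plates = n_source_plates,
                 yield_per_plate = yield_per_plate,
                 wells_per_assay_plate = wells_per_assay_plate,
                 cells_per_assay_well = cells_per_assay_well,
                 n_assay_plates = n),
            class = "capacity_plan")
}

#' @export
print.capacity_plan <- function(x, ...) {
  cat(sprintf("<capacity_plan> %d source plates x %.3g cells -> %d assay plates (%d x %g cells)\n",
              x$n_source_plates, x$yield_per_plate, x$n_assay_plates,
              x$wells_per_assay_plate, x$cells_per_assay_well))
  invisible(x)
}

#' Cells seeded per well from a suspension
#'
#' `concentration (cells/ml) x volume (ul) / 1000`, rounded to the
#' nearest integer.
#'
#' @param concentration cells per millilitre (> 0 unless volume is 0).
#' @param volume_ul dispensed volume in microlitres (>= 0).
#' @return integer cell count.
#' @examples
#' seeding_cells_per_well(30000, 100)  # 3000
#' @export
seeding_cells_per_well <- function(concentration, volume_ul) {
  if (concentration < 0 || volume_ul < 0)
    stop("inputs must be non-negative", call. = FALSE)
  as.integer(round(concentration * volume_ul / 1000))
}
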
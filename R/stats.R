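# Multivariate layer: trait-matrix assembly, correlation PCA with Kaiser
# retention, factorial-score distances, Pearson correlation with
# significance, and two-way ANOVA with Holm-Sidak simple effects.

.TRAIT_COLUMNS <- c("A", "B", "S", "H", "P", "HP", "Cha", "Chb", "TC",
                    "Carot", "FD", "deltaE")

#' Build the population-by-treatment trait matrix
#'
#' Averages the per-plant records over replicates within each
#' (population, treatment) cell, producing the matrix fed to the PCA and
#' correlation analyses: one row per cell (labelled `<pop><treatment>`,
#' e.g. `C0`, `I400`) and the twelve analysis variables in fixed order
#' A, B, S, H, P, HP, Cha, Chb, TC, Carot, FD, deltaE.
#'
#' @param records data.frame with `population`, `treatment_mM` and the 12
#'   trait columns, one row per plant.
#' @return numeric matrix (cells x 12).
#' @export
build_trait_matrix <- function(records) {
  missing <- setdiff(c("population", "treatment_mM", .TRAIT_COLUMNS),
                     names(records))
  if (length(missing)) {
    stop("records lack columns: ", paste(missing, collapse = ", "))
  }
  if (any(!stats::complete.cases(records[, .TRAIT_COLUMNS]))) {
    stop("records contain missing trait values")
  }
  pops <- unique(records$population)
  trs <- sort(unique(records$treatment_mM))
  rows <- list()
  for (pop in pops) {
    for (tr in trs) {
      sel <- records$population == pop & records$treatment_mM == tr
      if (!any(sel)) {
        stop(sprintf("design cell %s/%s mM has no replicates", pop, format(tr)))
      }
      rows[[paste0(pop, tr)]] <- colMeans(records[sel, .TRAIT_COLUMNS])
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- .TRAIT_COLUMNS
  out
}

#' Principal component analysis of the trait matrix
#'
#' Correlation-matrix PCA: columns are centred and scaled to unit
#' variance, components come from the singular value decomposition of the
#' standardised data, scores are the standardised data projected on the
#' loadings, and the number of retained components follows the Kaiser
#' criterion (eigenvalue > 1).  Loading signs are fixed so that each
#' column's largest-magnitude loading is positive, making scores
#' reproducible across eigensolvers.
#'
#' @param x numeric matrix (observations x variables), e.g. from
#'   [build_trait_matrix()].
#' @param standardise scale columns to unit variance (default `TRUE`,
#'   i.e. correlation PCA); `FALSE` gives covariance PCA.
#' @return object of class `"trait_pca"`: list with `eigenvalues`,
#'   `variance_pct`, `loadings`, `scores`, `retained`.
#' @export
pca_traits <- function(x, standardise = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("PCA needs at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (standardise && any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = standardise)
  eig <- pr$sdev^2
  load <- pr$rotation
  # sign convention: largest |loading| in each column positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pr$x, 2, flip, `*`)
  structure(list(
    eigenvalues = eig,
    variance_pct = 100 * eig / sum(eig),
    loadings = load,
    scores = scores,
    retained = sum(eig > 1)
  ), class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("Correlation PCA: %d components, %d retained (Kaiser)\n",
              length(x$eigenvalues), x$retained))
  cat(sprintf("  PC1..PC3 variance: %s%%\n",
              paste(sprintf("%.2f", x$variance_pct[1:min(3, length(x$variance_pct))]),
                    collapse = " / ")))
  invisible(x)
}

#' Euclidean distance between two factorial-score rows
#'
#' `D = sqrt((x2 - x1)^2 + (y2 - y1)^2 + (z2 - z1)^2)` over the first
#' `n_components` principal-component scores; used to quantify the
#' separation of the two populations under the same treatment.
#'
#' @param scores1,scores2 numeric score vectors (at least `n_components`
#'   long).
#' @param n_components number of leading components used (default 3).
#' @return non-negative scalar distance.
#' @examples
#' pc_distance(c(0, 0, 0), c(1, 2, 2))  # 3
#' @export
pc_distance <- function(scores1, scores2, n_components = 3) {
  if (length(scores1) < n_components || length(scores2) < n_components) {
    stop(sprintf("need at least %d components per score row", n_components))
  }
  i <- seq_len(n_components)
  sqrt(sum((as.numeric(scores2)[i] - as.numeric(scores1)[i])^2))
}

#' Pearson correlation matrix with significance flags
#'
#' Pairwise Pearson correlations over the per-plant records with
#' two-sided significance from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.  Zero-variance variables yield `NA`
#' correlations for their pairs.
#'
#' @param records data.frame or matrix of the analysis variables (only
#'   numeric trait columns are used if design columns are present).
#' @param alpha significance level for the flag matrix (default 0.05).
#' @return list with `r`, `p`, `significant` (logical, `p < alpha`,
#'   diagonal `FALSE`) and `n`.
#' @export
pearson_matrix <- function(records, alpha = 0.05) {
  x <- if (is.data.frame(records)) {
    keep <- intersect(.TRAIT_COLUMNS, names(records))
    if (!length(keep)) keep <- names(records)[vapply(records, is.numeric, TRUE)]
    as.matrix(records[, keep])
  } else {
    as.matrix(records)
  }
  n <- nrow(x)
  if (n < 3) stop("need at least 3 observations per pair")
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA
  r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  sig <- p < alpha & !is.na(p)
  diag(sig) <- FALSE
  list(r = r, p = p, significant = sig, n = n)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the raw p-values ascending and sets the i-th adjusted value to
#' `1 - (1 - p_i)^(m - i + 1)`, enforcing monotonicity by running maxima
#' and capping at 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the original order.
#' @examples
#' holm_sidak(c(0.01, 0.02, 0.04))  # 0.029701 0.039600 0.040000
#' @export
holm_sidak <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Compact letter display by insert-absorb.  `lvls` in display order;
# `sig` a symmetric logical matrix over lvls marking significantly
# different pairs.
compact_letters <- function(lvls, sig) {
  sets <- list(lvls)
  k <- length(lvls)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        if (!isTRUE(sig[i, j])) next
        li <- lvls[i]
        lj <- lvls[j]
        new_sets <- list()
        for (s in sets) {
          if (li %in% s && lj %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, li)), list(setdiff(s, lj)))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        # absorb sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) {
          for (b in seq_along(new_sets)) {
            if (a != b && keep[b] &&
                all(new_sets[[a]] %in% new_sets[[b]]) &&
                (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
              keep[a] <- FALSE
              break
            }
          }
        }
        sets <- unique(new_sets[keep])
      }
    }
  }
  # order sets by the first level they contain, assign letters
  first_idx <- vapply(sets, function(s) min(match(s, lvls)), numeric(1))
  sets <- sets[order(first_idx)]
  letters_out <- stats::setNames(rep("", k), lvls)
  for (si in seq_along(sets)) {
    for (lv in sets[[si]]) {
      letters_out[lv] <- paste0(letters_out[lv], letters[si])
    }
  }
  letters_out
}

#' Two-way ANOVA with Holm-Sidak simple effects and compact letters
#'
#' Full factorial analysis of one trait over population and treatment:
#' omnibus F tests (population, treatment, interaction), pairwise
#' simple-effect comparisons of treatments within each population and of
#' populations within each treatment using the pooled residual error,
#' Holm-Sidak step-down adjustment within each comparison family, compact
#' letter displays per population (insert-absorb, treatments ordered by
#' concentration), and an asterisk flag where the populations differ
#' within a treatment.
#'
#' @param values numeric response vector, one entry per plant.
#' @param population,treatment design labels aligned with `values`.
#' @param alpha significance level (default 0.05).
#' @return object of class `"anova_report"`: list with `anova_table`,
#'   `within_population` (pairwise treatment comparisons per population),
#'   `between_population` (one comparison per treatment, `significant`
#'   flag), and `letters` (compact letters per population x treatment).
#' @export
two_way_anova <- function(values, population, treatment, alpha = 0.05) {
  df <- data.frame(y = values,
                   population = factor(population),
                   treatment = factor(treatment,
                                      levels = sort(unique(as.numeric(treatment)))))
  counts <- table(df$population, df$treatment)
  if (any(counts < 2)) {
    stop("every population x treatment cell needs >= 2 replicates")
  }
  fit <- stats::lm(y ~ population * treatment, data = df)
  an <- stats::anova(fit)
  anova_table <- data.frame(
    term = c("population", "treatment", "interaction"),
    df = an$Df[1:3],
    F = an$`F value`[1:3],
    p = an$`Pr(>F)`[1:3]
  )
  mse <- an$`Mean Sq`[4]
  dfe <- an$Df[4]
  cellmeans <- tapply(df$y, list(df$population, df$treatment), mean)

  pairwise_p <- function(m1, m2, n1, n2) {
    if (mse <= 0) return(as.numeric(m1 != m2) * 0 + as.numeric(m1 == m2))
    tt <- (m1 - m2) / sqrt(mse * (1 / n1 + 1 / n2))
    2 * stats::pt(-abs(tt), dfe)
  }

  pops <- levels(df$population)
  trs <- levels(df$treatment)

  # treatments within population
  within <- list()
  for (pop in pops) {
    combs <- utils::combn(trs, 2)
    raw <- numeric(ncol(combs))
    diffs <- numeric(ncol(combs))
    for (k in seq_len(ncol(combs))) {
      t1 <- combs[1, k]; t2 <- combs[2, k]
      diffs[k] <- cellmeans[pop, t1] - cellmeans[pop, t2]
      raw[k] <- pairwise_p(cellmeans[pop, t1], cellmeans[pop, t2],
                           counts[pop, t1], counts[pop, t2])
    }
    adj <- holm_sidak(raw)
    within[[pop]] <- data.frame(
      population = pop,
      treatment_1 = combs[1, ], treatment_2 = combs[2, ],
      diff = diffs, p_raw = raw, p_adj = adj,
      significant = adj < alpha
    )
  }
  within <- do.call(rbind, within)
  rownames(within) <- NULL

  # populations within treatment (one family across the treatments)
  if (length(pops) != 2) {
    between <- NULL
  } else {
    raw <- numeric(length(trs))
    diffs <- numeric(length(trs))
    for (k in seq_along(trs)) {
      diffs[k] <- cellmeans[pops[1], trs[k]] - cellmeans[pops[2], trs[k]]
      raw[k] <- pairwise_p(cellmeans[pops[1], trs[k]], cellmeans[pops[2], trs[k]],
                           counts[pops[1], trs[k]], counts[pops[2], trs[k]])
    }
    adj <- holm_sidak(raw)
    between <- data.frame(
      treatment = trs, diff = diffs, p_raw = raw, p_adj = adj,
      significant = adj < alpha,
      flag = ifelse(adj < alpha, "*", "")
    )
  }

  # compact letters per population
  letters_df <- list()
  for (pop in pops) {
    sub <- within[within$population == pop, ]
    sig <- matrix(FALSE, length(trs), length(trs), dimnames = list(trs, trs))
    for (k in seq_len(nrow(sub))) {
      sig[sub$treatment_1[k], sub$treatment_2[k]] <- sub$significant[k]
      sig[sub$treatment_2[k], sub$treatment_1[k]] <- sub$significant[k]
    }
    lets <- compact_letters(trs, sig)
    letters_df[[pop]] <- data.frame(population = pop, treatment = trs,
                                    letter = unname(lets))
  }
  letters_df <- do.call(rbind, letters_df)
  rownames(letters_df) <- NULL

  structure(list(anova_table = anova_table,
                 within_population = within,
                 between_population = between,
                 letters = letters_df,
                 alpha = alpha),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat("Two-way ANOVA\n")
  print(x$anova_table, row.names = FALSE)
  cat("\nCompact letters (treatments within population):\n")
  print(x$letters, row.names = FALSE)
  if (!is.null(x$between_population)) {
    sig <- x$between_population$treatment[x$between_population$significant]
    cat(sprintf("\nPopulations differ (alpha = %.2f) at: %s\n", x$alpha,
                if (length(sig)) paste(sig, collapse = ", ") else "none"))
  }
  invisible(x)
}
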
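#' Mixed-design ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate mixed-model ANOVA on a balanced table of
#' participant-by-cell means: between-participant factors, within-
#' participant (repeated) factors, sums of squares from the standard
#' error-stratum decomposition, Greenhouse-Geisser epsilon applied to every
#' effect involving a within factor, and generalized eta-squared (the
#' SS_effect / (SS_effect + sum of all error SS) convention for designs with
#' only manipulated factors).
#'
#' @param cell_means Data.frame with one row per participant x within-cell,
#'   containing `id_col`, `dv_col`, and all factor columns.
#' @param within Character vector of within-participant factor columns (may
#'   be empty for a pure between design).
#' @param between Character vector of between-participant factor columns
#'   (may be empty).
#' @param dv_col,id_col Column names of the dependent variable and the
#'   participant identifier.
#' @return An object of class `anova_table`: data.frame with one row per
#'   effect (`effect`, `df1`, `df2`, `epsilon`, `df1_gg`, `df2_gg`, `F`,
#'   `p`, `ges`, and the raw `ss_effect`, `ss_error`).
#' @examples
#' d <- expand.grid(participant = paste0("P", 1:6), cond = c("a", "b"))
#' d$group <- rep(c("g1", "g2"), each = 2)[match(d$participant, unique(d$participant))]
#' d$value <- rnorm(nrow(d))
#' mixed_anova(d, within = "cond", between = "group")
#' @export
mixed_anova <- function(cell_means, within = character(), between = character(),
                        dv_col = "value", id_col = "participant") {
  df <- as.data.frame(cell_means)
  for (f in c(within, between, id_col)) df[[f]] <- factor(df[[f]])
  df$.y <- df[[dv_col]]
  if (anyNA(df$.y)) stop("missing cell means")

  # balance check: one observation per participant x within-cell
  if (length(within)) {
    tab <- table(df[c(id_col, within)])
    if (any(tab != 1L))
      stop("unbalanced within-cells: need exactly one value per participant ",
           "and within-factor combination")
  } else if (anyDuplicated(df[[id_col]])) {
    stop("pure between design needs one row per participant")
  }

  rhs_terms <- c(between, within)
  fixed <- paste(rhs_terms, collapse = " * ")
  if (length(within)) {
    err <- paste0("Error(", id_col, "/(",
                  paste(within, collapse = " * "), "))")
    form <- stats::as.formula(paste(".y ~", fixed, "+", err))
  } else {
    form <- stats::as.formula(paste(".y ~", fixed))
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)

  # flatten the stratum tables into (effect, df, ss) plus residuals
  rows <- list()
  resid_ss <- c()
  strata <- if (length(within)) sm else list(`Error: Within` = sm)
  for (s_name in names(strata)) {
    tab <- strata[[s_name]][[1]]
    eff_names <- trimws(rownames(tab))
    for (i in seq_along(eff_names)) {
      nm <- eff_names[i]
      if (nm == "Residuals") {
        resid_ss[s_name] <- tab[i, "Sum Sq"]
      } else {
        rows[[nm]] <- data.frame(effect = nm, df1 = tab[i, "Df"],
                                 ss_effect = tab[i, "Sum Sq"],
                                 df2 = tab[nrow(tab), "Df"],
                                 ss_error = tab[nrow(tab), "Sum Sq"],
                                 stratum = s_name)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  total_error_ss <- sum(resid_ss)

  eps_map <- gg_epsilons(df, within, between, id_col)
  out$epsilon <- vapply(out$effect, function(e) {
    w_in <- within[vapply(within, function(f)
      f %in% strsplit(e, ":", fixed = TRUE)[[1]], logical(1))]
    if (!length(w_in)) return(NA_real_)
    eps_map[[paste(sort(w_in), collapse = ":")]]
  }, numeric(1))

  out$df1_gg <- ifelse(is.na(out$epsilon), out$df1, out$epsilon * out$df1)
  out$df2_gg <- ifelse(is.na(out$epsilon), out$df2, out$epsilon * out$df2)
  out$F <- (out$ss_effect / out$df1) / (out$ss_error / out$df2)
  out$p <- stats::pf(out$F, out$df1_gg, out$df2_gg, lower.tail = FALSE)
  out$ges <- out$ss_effect / (out$ss_effect + total_error_ss)
  out <- out[, c("effect", "df1", "df2", "epsilon", "df1_gg", "df2_gg",
                 "F", "p", "ges", "ss_effect", "ss_error")]
  class(out) <- c("anova_table", "data.frame")
  out
}

# Greenhouse-Geisser epsilon per within effect, from the pooled (across
# between groups) covariance matrix of the participant x within-cell scores.
gg_epsilons <- function(df, within, between, id_col) {
  if (!length(within)) return(list())
  lev <- lapply(within, function(f) levels(df[[f]]))
  names(lev) <- within
  grid <- do.call(expand.grid, c(lev, KEEP.OUT.ATTRS = FALSE,
                                 stringsAsFactors = FALSE))
  cell_key <- function(d) {
    do.call(paste, c(lapply(within, function(f) as.character(d[[f]])),
                     sep = "\r"))
  }
  grid_key <- do.call(paste, c(grid, sep = "\r"))
  ids <- unique(df[[id_col]])
  Y <- matrix(NA_real_, length(ids), nrow(grid),
              dimnames = list(as.character(ids), NULL))
  key <- cell_key(df)
  col <- match(key, grid_key)
  Y[cbind(match(as.character(df[[id_col]]), rownames(Y)), col)] <- df$.y

  # pooled covariance within between-groups
  if (length(between)) {
    grp <- df[!duplicated(df[[id_col]]), , drop = FALSE]
    grp_key <- do.call(paste, c(lapply(between, function(f)
      as.character(grp[[f]])), sep = "\r"))
    names(grp_key) <- as.character(grp[[id_col]])
    grp_of <- grp_key[rownames(Y)]
  } else {
    grp_of <- rep("all", nrow(Y))
  }
  S <- 0
  dof <- 0
  for (g in unique(grp_of)) {
    Yg <- Y[grp_of == g, , drop = FALSE]
    if (nrow(Yg) > 1) {
      S <- S + stats::cov(Yg) * (nrow(Yg) - 1)
      dof <- dof + nrow(Yg) - 1
    }
  }
  S <- S / dof

  orthonorm_contr <- function(L) {
    C <- stats::contr.helmert(L)
    t(sweep(C, 2, sqrt(colSums(C^2)), "/"))  # (L-1) x L, orthonormal rows
  }
  unit_row <- function(L) matrix(1 / sqrt(L), 1, L)

  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, function(x)
      paste(sort(x), collapse = ":"), simplify = FALSE)), recursive = FALSE)
  eps <- list()
  for (e in effects) {
    in_eff <- strsplit(e, ":", fixed = TRUE)[[1]]
    # columns of Y follow expand.grid order: first factor varies fastest,
    # so the Kronecker product runs over factors in reverse order
    M <- matrix(1, 1, 1)
    for (f in rev(within)) {
      L <- length(lev[[f]])
      M <- kronecker(M, if (f %in% in_eff) orthonorm_contr(L) else unit_row(L))
    }
    E <- M %*% S %*% t(M)
    d <- nrow(M)
    eps[[e]] <- if (d == 1) 1 else
      min(1, (sum(diag(E)))^2 / (d * sum(E^2)))
  }
  eps
}

#' @export
print.anova_table <- function(x, ...) {
  y <- x
  y$F <- round(y$F, 2)
  y$p <- signif(y$p, 3)
  y$ges <- round(y$ges, 3)
  y$epsilon <- round(y$epsilon, 3)
  y$df1_gg <- round(y$df1_gg, 2)
  y$df2_gg <- round(y$df2_gg, 2)
  print.data.frame(y[, c("effect", "df1_gg", "df2_gg", "epsilon", "F",
                         "p", "ges")], row.names = FALSE)
  invisible(x)
}
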
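# tensor-product B-spline surface over field (row, col); coefficients are
# treated as one iid random effect (P-spline approximation of the
# 2-D spline spatial adjustment)
spatial_basis <- function(row, col, df = 8L) {
  bs_safe <- function(v) {
    k <- min(df, max(3L, length(unique(v))))
    if (length(unique(v)) < 3L)
      return(matrix(1, length(v), 1L))
    splines::bs(v, df = k, intercept = TRUE)
  }
  Br <- bs_safe(row); Bc <- bs_safe(col)
  # row-wise Kronecker (tensor) product
  out <- matrix(0, length(row), ncol(Br) * ncol(Bc))
  k <- 1L
  for (i in seq_len(ncol(Br))) for (j in seq_len(ncol(Bc))) {
    out[, k] <- Br[, i] * Bc[, j]; k <- k + 1L
  }
  out / sqrt(mean(rowSums(out^2)))   # scale so the implied variance is O(1)
}

#' Genomic BLUP with spatial and year adjustment
#'
#' Fits, per trait, the record-level mixed model
#' `y = mu + u_g + u_year + u_spatial + e` with `u_g ~ N(0, K sigma2_g)`
#' (K a genomic relationship matrix), iid year effects, a tensor-product
#' B-spline field surface with iid random coefficients, and iid residuals.
#' Variance components are estimated by direct REML (quasi-Newton on log
#' variances); predictions come from the mixed-model equations evaluated
#' at the REML estimates.
#'
#' @param records long phenotype data frame with columns `accession_id`,
#'   `trait`, `value`, `year`, and (for the spatial term) `row`, `col`.
#' @param kinship n x n relationship matrix with dimnames covering all
#'   phenotyped accessions (see [vanraden_kinship()]).
#' @param trait trait name to fit.
#' @param include_spatial model the field surface (default TRUE; needs
#'   `row`/`col` columns).
#' @param spline_df marginal B-spline basis dimension (default 8).
#' @param varcomp optional named vector
#'   `c(genomic=, year=, spatial=, residual=)` of fixed variance
#'   components; skips REML (used for limit-case checks).
#' @return object of class `gblup_fit`: `blups` (data frame
#'   `accession_id`, `blup`), `varcomp`, `loglik`, `loglik_path`, `trait`,
#'   `n_records`.
#' @export
fit_gblup <- function(records, kinship, trait, include_spatial = TRUE,
                      spline_df = 8L, varcomp = NULL) {
  rec <- records[records$trait == trait & !is.na(records$value), ,
                 drop = FALSE]
  if (!nrow(rec)) stop("no records for trait ", trait)
  acc <- sort(unique(rec$accession_id))
  if (!all(acc %in% rownames(kinship)))
    stop("kinship does not cover accession(s): ",
         paste(utils::head(setdiff(acc, rownames(kinship)), 3), collapse = ", "))
  K <- kinship[acc, acc, drop = FALSE]
  N <- nrow(rec)
  y <- rec$value
  Zg <- outer(rec$accession_id, acc, "==") * 1
  Cg <- Zg %*% K %*% t(Zg)

  comps <- list(genomic = Cg)
  years <- unique(rec$year)
  if (length(years) >= 2L) {
    Zy <- outer(rec$year, years, "==") * 1
    comps$year <- tcrossprod(Zy)
  }
  use_spatial <- include_spatial && all(c("row", "col") %in% names(rec)) &&
    length(unique(paste(rec$row, rec$col))) >= 4L
  if (use_spatial) {
    B <- spatial_basis(rec$row, rec$col, spline_df)
    comps$spatial <- tcrossprod(B)
  }

  X <- matrix(1, N, 1)
  vy <- stats::var(y)
  nm <- c(names(comps), "residual")

  loglik_path <- numeric(0)
  reml_ll <- function(logv) {
    v <- exp(logv)
    V <- diag(v[length(v)], N)
    for (i in seq_along(comps)) V <- V + v[i] * comps[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    XtViX <- crossprod(X, Vi_X)
    bhat <- solve(XtViX, crossprod(Vi_X, y))
    Py <- Vi_y - Vi_X %*% solve(XtViX, crossprod(Vi_X, y))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus +
                    sum(y * Py))
    loglik_path <<- c(loglik_path, as.numeric(ll))
    as.numeric(ll)
  }

  if (is.null(varcomp)) {
    k <- length(comps) + 1L
    init <- log(rep(vy / k, k))
    opt <- stats::optim(init, reml_ll, method = "L-BFGS-B",
                        lower = log(vy) - 20, upper = log(vy) + 6,
                        control = list(fnscale = -1, maxit = 200))
    v <- exp(opt$par)
    ll <- opt$value
  } else {
    v <- unname(varcomp[nm])
    if (anyNA(v)) stop("varcomp must name: ", paste(nm, collapse = ", "))
    ll <- reml_ll(log(pmax(v, 1e-12)))
  }
  names(v) <- nm

  V <- diag(v["residual"], N)
  for (i in seq_along(comps)) V <- V + v[i] * comps[[i]]
  ch <- chol(V)
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtViX <- crossprod(X, Vi_X)
  bhat <- solve(XtViX, crossprod(Vi_X, y))
  resid_part <- Vi_y - Vi_X %*% solve(XtViX, crossprod(Vi_X, y))
  ug <- v["genomic"] * K %*% crossprod(Zg, resid_part)

  structure(list(
    blups = data.frame(accession_id = acc, blup = as.numeric(ug),
                       stringsAsFactors = FALSE),
    mu = as.numeric(bhat), varcomp = v, loglik = ll,
    loglik_path = loglik_path, trait = trait, n_records = N,
    components = names(comps)),
    class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit for ", x$trait, ": ", x$n_records, " records, ",
      nrow(x$blups), " accessions\n  variance components: ",
      paste(names(x$varcomp), fmt_num(x$varcomp), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Compare accession genetic values across subgroups
#'
#' One-way ANOVA omnibus test plus Tukey HSD pairwise comparisons of
#' per-accession values (typically GBLUPs) across panel subgroups, with
#' per-subgroup descriptive summaries. Omnibus p-values below machine
#' precision are reported as `.Machine$double.xmin`, never literal zero.
#'
#' @param values data frame `accession_id`, `blup` (e.g. from
#'   [fit_gblup()]`$blups`), or a `gblup_fit`.
#' @param meta metadata data frame.
#' @return list of class `subgroup_comparison`: `omnibus_p`, `anova`,
#'   `tukey`, `descriptives`.
#' @export
subgroup_compare <- function(values, meta) {
  if (inherits(values, "gblup_fit")) values <- values$blups
  df <- merge(values, meta, by = "accession_id")
  df <- df[!is.na(df$blup), , drop = FALSE]
  sizes <- table(df$subgroup)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need >= 2 subgroups with >= 2 accessions each")
  df$subgroup <- factor(df$subgroup)
  fit <- stats::aov(blup ~ subgroup, data = df)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  p <- max(p, .Machine$double.xmin)
  desc <- do.call(rbind, lapply(split(df$blup, df$subgroup), function(v)
    data.frame(n = length(v), min = min(v), mean = mean(v), max = max(v))))
  desc <- cbind(subgroup = rownames(desc), desc)
  rownames(desc) <- NULL
  structure(list(omnibus_p = p, anova = fit,
                 tukey = stats::TukeyHSD(fit)$subgroup,
                 descriptives = desc),
            class = "subgroup_comparison")
}

#' @export
print.subgroup_comparison <- function(x, ...) {
  cat("subgroup comparison: omnibus ANOVA p =", format(x$omnibus_p), "\n")
  print(x$descriptives)
  invisible(x)
}

#' Pairwise trait correlations
#'
#' Signed Pearson correlations between per-accession trait values with
#' two-sided test p-values.
#'
#' @param wide data frame or matrix, accessions x traits.
#' @return list with `r` (correlation matrix), `p` (p-value matrix),
#'   `n` (paired-observation counts).
#' @export
trait_correlations <- function(wide) {
  m <- as.matrix(wide)
  t_names <- colnames(m)
  kk <- ncol(m)
  r <- diag(1, kk); p <- matrix(NA_real_, kk, kk); nn <- matrix(0L, kk, kk)
  dimnames(r) <- dimnames(p) <- dimnames(nn) <- list(t_names, t_names)
  for (i in seq_len(kk)) for (j in seq_len(kk)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    nn[i, j] <- sum(ok)
    if (i == j) next
    if (sum(ok) < 3L) stop("fewer than 3 paired observations for ",
                           t_names[i], " vs ", t_names[j])
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0)
      stop("constant trait: ", t_names[if (stats::sd(m[ok, i]) == 0) i else j])
    ct <- stats::cor.test(m[ok, i], m[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p, n = nn)
}
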
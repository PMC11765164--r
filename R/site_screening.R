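#' Discretise beta values into equal-width bins on [0, 1]
#'
#' Bin k (0-based) covers \[k/n_bins, (k+1)/n_bins); the value 1.0 falls in
#' the last bin. Binning turns the continuous methylation fraction into the
#' categorical variable whose tissue association the chi-square screen tests.
#'
#' @param values numeric vector of beta values in \[0, 1\] (NA allowed).
#' @param n_bins number of bins, >= 2.
#' @return integer vector of 0-based bin indices (NA preserved).
#' @export
bin_beta_values <- function(values, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad) > 0)
    stop(sprintf("beta value out of [0,1] at position %d: %g",
                 bad[1L], values[bad[1L]]), call. = FALSE)
  pmin(as.integer(floor(values * n_bins)), n_bins - 1L)
}

#' Chi-square test of one CpG site's tissue specificity
#'
#' Builds a bins x tissues contingency table from the binned beta values of
#' healthy samples, computes the Pearson statistic
#' \eqn{\sum (O - E)^2 / E} over cells with expected count > 0, and the
#' upper-tail p-value of the chi-square distribution. Degrees of freedom are
#' \code{(occupied_bins - 1) * (occupied_tissues - 1)}, where occupied means
#' a nonzero margin: bins (or tissues) that receive no observations carry no
#' information and are dropped. Missing values are removed pairwise with
#' their labels before tabulation.
#'
#' @param site_values numeric beta values of one site across samples.
#' @param tissue_labels parallel tissue labels.
#' @param n_bins number of equal-width bins (default 10).
#' @return list (class \code{chisq_site}) with \code{statistic}, \code{df},
#'   \code{p_value}, and the contingency \code{table}.
#' @export
chi_square_tissue_test <- function(site_values, tissue_labels, n_bins = 10L) {
  if (length(site_values) != length(tissue_labels))
    stop("site_values and tissue_labels lengths differ", call. = FALSE)
  keep <- !is.na(site_values) & !is.na(tissue_labels)
  v <- site_values[keep]
  lab <- as.character(tissue_labels[keep])
  if (length(unique(lab)) < 2)
    stop("need at least two distinct tissues", call. = FALSE)
  bins <- bin_beta_values(v, n_bins)
  tab <- table(factor(bins, levels = 0:(n_bins - 1L)), lab)
  res <- chisq_stat(tab)
  structure(c(res, list(table = tab)), class = "chisq_site")
}

# Pearson chi-square on a counts matrix, dropping empty rows/columns.
chisq_stat <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (df <= 0)
    return(list(statistic = 0, df = 0L, p_value = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Screen for tissue-specific CpG sites (stage 1)
#'
#' Restricts to healthy samples, runs \code{\link{chi_square_tissue_test}}
#' on every site, and selects the sites whose p-value falls strictly below
#' \code{tau_p} (default 0.01). The healthy-only restriction keeps disease
#' effects from masquerading as tissue effects.
#'
#' @param matrix a \code{\link{methyl_matrix}}.
#' @param metadata sample metadata (sample_id, tissue, status).
#' @param tau_p significance threshold in (0, 1\]; sites with
#'   \code{p_value < tau_p} are selected. \code{tau_p = 0} is accepted and
#'   selects nothing.
#' @param n_bins bins for discretisation.
#' @return list (class \code{tissue_screen}) with \code{results} (data.frame
#'   site_id, statistic, df, p_value), \code{selected_sites} (ascending
#'   p-value, ties broken by site_id), \code{tau_p}, \code{n_bins}.
#' @examples
#' betas <- read_beta_matrix(system.file("extdata",
#'   "synthetic_demo_betas.tsv", package = "methyldx"))
#' meta <- read_sample_metadata(system.file("extdata",
#'   "synthetic_demo_metadata.tsv", package = "methyldx"))
#' screen_tissue_specific(betas, meta, tau_p = 0.05)
#' @export
screen_tissue_specific <- function(matrix, metadata, tau_p = 0.01,
                                   n_bins = 10L) {
  stopifnot(inherits(matrix, "methyl_matrix"))
  if (tau_p < 0 || tau_p > 1)
    stop("tau_p must be in [0, 1]", call. = FALSE)
  md <- metadata[match(rownames(matrix), metadata$sample_id), ]
  if (anyNA(md$sample_id))
    stop("metadata is missing samples present in the matrix", call. = FALSE)
  healthy <- which(md$status == 0L)
  if (length(healthy) == 0) stop("no healthy samples", call. = FALSE)
  lab <- md$tissue[healthy]
  if (length(unique(lab)) < 2)
    stop("need >= 2 tissues among healthy samples", call. = FALSE)

  x <- unclass(matrix)[healthy, , drop = FALSE]
  labf <- factor(lab)
  nt <- nlevels(labf)
  lab_i <- as.integer(labf)
  nb <- as.integer(n_bins)

  site_ids <- colnames(x)
  stat <- df <- pv <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    keep <- !is.na(v)
    bins <- bin_beta_values(v[keep], nb)
    # counts laid out bins x tissues
    cnt <- tabulate(bins + 1L + nb * (lab_i[keep] - 1L), nbins = nb * nt)
    res <- chisq_stat(base::matrix(cnt, nrow = nb, ncol = nt))
    stat[j] <- res$statistic; df[j] <- res$df; pv[j] <- res$p_value
  }
  results <- data.frame(site_id = site_ids, statistic = stat, df = df,
                        p_value = pv, stringsAsFactors = FALSE)
  structure(list(results = results,
                 selected_sites = select_by_pvalue(results, tau_p),
                 tau_p = tau_p, n_bins = nb),
            class = "tissue_screen")
}

# selection rule: strictly below tau_p, ordered by ascending p then site_id
select_by_pvalue <- function(results, tau_p) {
  sel <- results[results$p_value < tau_p, , drop = FALSE]
  sel$site_id[order(sel$p_value, sel$site_id)]
}

#' @export
print.tissue_screen <- function(x, ...) {
  cat(sprintf(
    "tissue_screen: %d sites tested, %d selected at p < %g (%d bins)\n",
    nrow(x$results), length(x$selected_sites), x$tau_p, x$n_bins))
  invisible(x)
}

#' Rank candidate sites by disease association within one tissue (stage 2)
#'
#' Fits an L2-regularised logistic regression of health status on the
#' candidate-site beta values, using only the samples of the given tissue.
#' Features are standardised to zero mean / unit variance within the tissue
#' before fitting (penalised coefficients are only comparable on a common
#' scale), the ridge penalty is \code{lambda = 1/n} so the fit stays
#' well-posed when candidates outnumber samples, and sites are ranked by
#' coefficient magnitude (or signed value) in descending order with a
#' lexicographic site_id tie-break. The first \code{top_k} sites form the
#' selected panel.
#'
#' @param matrix a \code{\link{methyl_matrix}}.
#' @param metadata sample metadata.
#' @param tissue tissue label to restrict to.
#' @param candidate_sites site ids to rank (typically the stage-1 selection).
#' @param top_k panel size (default 400).
#' @param signed if \code{TRUE}, rank by signed coefficient descending
#'   (keeps only hypermethylation-dominant associations at the top); default
#'   \code{FALSE} ranks by \code{|coefficient|}, which admits the
#'   hypomethylated disease sites that real panels contain.
#' @return list (class \code{disease_ranking}) with \code{tissue},
#'   \code{ranking} (data.frame site_id, coefficient, rank),
#'   \code{selected_sites}, \code{intercept}, \code{top_k}, \code{signed}.
#' @export
rank_disease_sites <- function(matrix, metadata, tissue, candidate_sites,
                               top_k = 400L, signed = FALSE) {
  stopifnot(inherits(matrix, "methyl_matrix"))
  if (length(candidate_sites) == 0)
    stop("candidate_sites is empty", call. = FALSE)
  missing_sites <- setdiff(candidate_sites, colnames(matrix))
  if (length(missing_sites) > 0)
    stop("candidate site not in matrix: ", missing_sites[1L], call. = FALSE)
  md <- metadata[match(rownames(matrix), metadata$sample_id), ]
  rows <- which(md$tissue == tissue)
  if (length(rows) == 0) stop("no samples of tissue ", tissue, call. = FALSE)
  y <- md$status[rows]
  if (length(unique(y)) < 2)
    stop("tissue ", tissue, " has a single health status", call. = FALSE)

  x <- unclass(matrix)[rows, candidate_sites, drop = FALSE]
  if (anyNA(x)) {           # mean-impute within tissue for the fit only
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2L]]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1            # constant sites carry no signal; coef -> 0
  xs <- scale(x, center = ctr, scale = scl)
  n <- nrow(xs)

  if (ncol(xs) >= 2) {
    fit <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                          lambda = 1 / n, standardize = FALSE,
                          thresh = 1e-12, maxit = 1e6)
    beta <- as.numeric(fit$beta)
    b0 <- as.numeric(fit$a0)
  } else {
    fit <- stats::glm(y ~ xs, family = stats::binomial())
    beta <- unname(stats::coef(fit)[2L])
    b0 <- unname(stats::coef(fit)[1L])
  }
  names(beta) <- candidate_sites

  key <- if (signed) beta else abs(beta)
  ord <- order(-key, candidate_sites)
  ranking <- data.frame(site_id = candidate_sites[ord],
                        coefficient = beta[ord],
                        rank = seq_along(ord),
                        stringsAsFactors = FALSE)
  k <- min(as.integer(top_k), nrow(ranking))
  structure(list(tissue = tissue, ranking = ranking,
                 selected_sites = ranking$site_id[seq_len(k)],
                 intercept = b0, top_k = as.integer(top_k), signed = signed),
            class = "disease_ranking")
}

#' @export
print.disease_ranking <- function(x, ...) {
  cat(sprintf(
    "disease_ranking (%s): %d candidates, top %d selected (%s ranking)\n",
    x$tissue, nrow(x$ranking), length(x$selected_sites),
    if (x$signed) "signed" else "|coefficient|"))
  invisible(x)
}

#' Per-site healthy/disease summary within one tissue
#'
#' Reports the healthy-group median (H_M), disease-group median (D_M), their
#' ratio D_M/H_M ("magnification", the fold change of disease over healthy
#' median methylation), and the per-group standard errors of the mean
#' (sd / sqrt(n)). Medians use the mean-of-middle-two convention for even n.
#' When H_M is 0 the magnification is undefined and reported as NA. A
#' bootstrap standard error of the median is available via
#' \code{se_method = "boot_median"}.
#'
#' @param matrix a \code{\link{methyl_matrix}}.
#' @param metadata sample metadata.
#' @param tissue tissue label.
#' @param site_id CpG site id.
#' @param se_method \code{"mean"} (default; SE of the mean) or
#'   \code{"boot_median"} (bootstrap SE of the median, 2000 resamples).
#' @param boot_n,boot_seed bootstrap resamples and seed.
#' @return data.frame with one row: site_id, tissue, H_M, D_M,
#'   magnification, H_SE, D_SE.
#' @export
site_summary <- function(matrix, metadata, tissue, site_id,
                         se_method = c("mean", "boot_median"),
                         boot_n = 2000L, boot_seed = 1L) {
  se_method <- match.arg(se_method)
  stopifnot(inherits(matrix, "methyl_matrix"))
  if (!site_id %in% colnames(matrix))
    stop("unknown site: ", site_id, call. = FALSE)
  md <- metadata[match(rownames(matrix), metadata$sample_id), ]
  rows <- which(md$tissue == tissue)
  v <- unclass(matrix)[rows, site_id]
  h <- v[md$status[rows] == 0L]; h <- h[!is.na(h)]
  d <- v[md$status[rows] == 1L]; d <- d[!is.na(d)]
  if (length(h) == 0 || length(d) == 0)
    stop("both statuses must be present in tissue ", tissue, call. = FALSE)

  se <- function(g) {
    if (se_method == "mean") {
      stats::sd(g) / sqrt(length(g))
    } else {
      set.seed(boot_seed)
      stats::sd(replicate(boot_n,
        stats::median(sample(g, length(g), replace = TRUE))))
    }
  }
  hm <- stats::median(h)
  dm <- stats::median(d)
  data.frame(site_id = site_id, tissue = tissue,
             H_M = hm, D_M = dm,
             magnification = if (hm > 0) dm / hm else NA_real_,
             H_SE = se(h), D_SE = se(d),
             stringsAsFactors = FALSE)
}

#' Summaries for a panel of sites
#'
#' @param matrix,metadata,tissue as \code{\link{site_summary}}.
#' @param site_ids sites to summarise.
#' @param gene_lookup optional named vector (see
#'   \code{\link{read_gene_lookup}}); adds a \code{gene} column.
#' @param ... passed to \code{\link{site_summary}}.
#' @return data.frame, one row per site.
#' @export
site_summary_table <- function(matrix, metadata, tissue, site_ids,
                               gene_lookup = NULL, ...) {
  out <- do.call(rbind, lapply(site_ids, function(s)
    site_summary(matrix, metadata, tissue, s, ...)))
  if (!is.null(gene_lookup))
    out$gene <- unname(gene_lookup[out$site_id])
  out
}
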
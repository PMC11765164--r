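#' Configuration for the synthetic methylation cohort generator
#'
#' Defines a multi-tissue healthy/disease cohort of 450K-style beta values
#' with planted effects. Every non-planted site shares one mean across all
#' tissues and statuses. Each planted tissue-specific site is assigned one
#' signature tissue (round-robin over \code{tissues}) whose healthy mean is
#' offset by \code{tissue_shift}. Each planted disease-specific site (a
#' subset of the tissue-specific sites, per tissue) additionally shifts its
#' mean by \code{disease_shift} in the disease samples of its signature
#' tissue, with the sign drawn at random per site so both hyper- and
#' hypo-methylation occur, as in real disease panels where fold changes fall
#' on both sides of 1.
#'
#' Per-cell noise is beta-distributed: a cell with true mean \eqn{\mu} is
#' drawn from Beta(\eqn{\mu\phi}, \eqn{(1-\mu)\phi}) where \eqn{\phi} is
#' \code{dispersion}, so values are bounded in (0,1) without clipping and the
#' marginal spread at \eqn{\phi = 50} (sd about 0.06 at \eqn{\mu = 0.5})
#' matches typical between-sample array variability. A truncated-normal
#' alternative is available via \code{noise = "truncnorm"}.
#'
#' All randomness derives from the single root \code{seed}: each generation
#' stage k re-seeds with \code{(seed + 77003 * k) mod (2^31 - 1)}, so cohorts
#' are reproducible bit-for-bit and stages are independent of each other's
#' draw counts.
#'
#' @param tissues tissue labels (default: the six-tissue vocabulary).
#' @param n_healthy_per_tissue,n_disease_per_tissue samples per tissue.
#' @param n_sites total CpG sites.
#' @param n_tissue_specific planted tissue-discriminating sites.
#' @param n_disease_specific_per_tissue planted disease-shifted sites per
#'   tissue, drawn from that tissue's share of the tissue-specific set.
#' @param baseline_beta_low,baseline_beta_high range of per-site baseline
#'   means, default 0.04-0.79 (the span of healthy medians seen on real
#'   disease-panel sites).
#' @param tissue_shift mean beta offset of a planted tissue site in its
#'   signature tissue (default 0.25).
#' @param disease_shift mean beta offset of a planted disease site in the
#'   disease samples of its tissue (default 0.2; sign random per site).
#' @param dispersion beta-distribution concentration \eqn{\phi} (default 50).
#' @param missing_rate fraction of cells set missing (default 0).
#' @param noise \code{"beta"} (default) or \code{"truncnorm"}.
#' @param seed root integer seed.
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(tissues = default_tissues(),
                          n_healthy_per_tissue = 50,
                          n_disease_per_tissue = 50,
                          n_sites = 2000,
                          n_tissue_specific = 200,
                          n_disease_specific_per_tissue = 20,
                          baseline_beta_low = 0.04,
                          baseline_beta_high = 0.79,
                          tissue_shift = 0.25,
                          disease_shift = 0.2,
                          dispersion = 50,
                          missing_rate = 0,
                          noise = c("beta", "truncnorm"),
                          seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(tissues = tissues,
              n_healthy_per_tissue = as.integer(n_healthy_per_tissue),
              n_disease_per_tissue = as.integer(n_disease_per_tissue),
              n_sites = as.integer(n_sites),
              n_tissue_specific = as.integer(n_tissue_specific),
              n_disease_specific_per_tissue =
                as.integer(n_disease_specific_per_tissue),
              baseline_beta_low = baseline_beta_low,
              baseline_beta_high = baseline_beta_high,
              tissue_shift = tissue_shift,
              disease_shift = disease_shift,
              dispersion = dispersion,
              missing_rate = missing_rate,
              noise = noise,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (length(tissues) < 1 || anyDuplicated(tissues))
      stop("tissues must be a non-empty set of unique labels", call. = FALSE)
    if (n_healthy_per_tissue < 1 || n_disease_per_tissue < 0 || n_sites < 1)
      stop("sample and site counts must be positive", call. = FALSE)
    if (!(n_disease_specific_per_tissue * length(tissues) <=
            n_tissue_specific && n_tissue_specific <= n_sites))
      stop("need n_disease_specific_per_tissue * n_tissues <= ",
           "n_tissue_specific <= n_sites", call. = FALSE)
    if (baseline_beta_low <= 0 || baseline_beta_high >= 1 ||
        baseline_beta_low >= baseline_beta_high)
      stop("baseline beta range must satisfy 0 < low < high < 1",
           call. = FALSE)
    if (missing_rate < 0 || missing_rate >= 1)
      stop("missing_rate must be in [0, 1)", call. = FALSE)
    if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  })
  cfg
}

# stage sub-seed from the root seed (documented in ?cohort_config)
sub_seed <- function(seed, k) (as.double(seed) + 77003 * k) %% 2147483647

# means are kept inside [MEAN_EPS, 1 - MEAN_EPS] so beta noise stays proper
MEAN_EPS <- 0.02

clip_mean <- function(m) pmin(pmax(m, MEAN_EPS), 1 - MEAN_EPS)

draw_cells <- function(mu, dispersion, noise) {
  # mu: vector of true means, one draw each
  if (noise == "beta") {
    stats::rbeta(length(mu), mu * dispersion, (1 - mu) * dispersion)
  } else {
    sd <- sqrt(mu * (1 - mu) / (dispersion + 1))
    pmin(pmax(stats::rnorm(length(mu), mu, sd), 0), 1)
  }
}

#' Generate a synthetic multi-tissue methylation cohort
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{betas} (a \code{\link{methyl_matrix}} of
#'   \code{(n_healthy + n_disease) * n_tissues} samples by \code{n_sites}
#'   sites), \code{metadata} (sample_id, tissue, status) and \code{truth}
#'   (ground-truth manifest: \code{tissue_specific_sites},
#'   \code{disease_specific_sites} per tissue, and the true mean arrays
#'   \code{healthy_means}/\code{disease_means}, sites x tissues).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  nt <- length(cfg$tissues)
  site_ids <- sprintf("cg%08d", seq_len(cfg$n_sites))

  # stage 1: baseline means and planted-site layout
  set.seed(sub_seed(cfg$seed, 1))
  baseline <- stats::runif(cfg$n_sites, cfg$baseline_beta_low,
                           cfg$baseline_beta_high)
  ts_idx <- if (cfg$n_tissue_specific > 0)
    sort(sample.int(cfg$n_sites, cfg$n_tissue_specific)) else integer(0)
  sig_tissue <- rep(seq_len(nt), length.out = length(ts_idx))

  healthy_means <- matrix(rep(baseline, nt), ncol = nt,
                          dimnames = list(site_ids, cfg$tissues))
  if (length(ts_idx) > 0) {
    shifted <- ifelse(baseline[ts_idx] + cfg$tissue_shift <= 1 - MEAN_EPS,
                      baseline[ts_idx] + cfg$tissue_shift,
                      baseline[ts_idx] - cfg$tissue_shift)
    healthy_means[cbind(ts_idx, sig_tissue)] <- clip_mean(shifted)
  }

  # stage 2: disease sites and disease-shift signs
  set.seed(sub_seed(cfg$seed, 2))
  disease_means <- healthy_means
  ds_sites <- stats::setNames(vector("list", nt), cfg$tissues)
  for (t in seq_len(nt)) {
    pool <- ts_idx[sig_tissue == t]
    if (cfg$n_disease_specific_per_tissue > 0) {
      pick <- sort(sample(pool, cfg$n_disease_specific_per_tissue))
      sgn <- sample(c(-1, 1), length(pick), replace = TRUE)
      m <- healthy_means[pick, t] + sgn * cfg$disease_shift
      flip <- m < MEAN_EPS | m > 1 - MEAN_EPS
      m[flip] <- healthy_means[pick, t][flip] - sgn[flip] * cfg$disease_shift
      disease_means[cbind(pick, t)] <- clip_mean(m)
      ds_sites[[t]] <- site_ids[pick]
    } else ds_sites[[t]] <- character(0)
  }

  # stage 3: cell values
  set.seed(sub_seed(cfg$seed, 3))
  n_per_t <- cfg$n_healthy_per_tissue + cfg$n_disease_per_tissue
  n <- n_per_t * nt
  tissue_of <- rep(seq_len(nt), each = n_per_t)
  status_of <- rep(rep(c(0L, 1L), c(cfg$n_healthy_per_tissue,
                                    cfg$n_disease_per_tissue)), nt)
  sample_ids <- sprintf("%s_%s%03d", cfg$tissues[tissue_of],
                        ifelse(status_of == 0L, "h", "d"),
                        unlist(lapply(seq_len(nt), function(t)
                          c(seq_len(cfg$n_healthy_per_tissue),
                            seq_len(cfg$n_disease_per_tissue)))))
  betas <- matrix(NA_real_, n, cfg$n_sites,
                  dimnames = list(sample_ids, site_ids))
  for (i in seq_len(n)) {
    mu <- if (status_of[i] == 0L) healthy_means[, tissue_of[i]]
          else disease_means[, tissue_of[i]]
    betas[i, ] <- draw_cells(mu, cfg$dispersion, cfg$noise)
  }

  # stage 4: missingness
  if (cfg$missing_rate > 0) {
    set.seed(sub_seed(cfg$seed, 4))
    betas[stats::runif(length(betas)) < cfg$missing_rate] <- NA_real_
  }

  metadata <- data.frame(sample_id = sample_ids,
                         tissue = cfg$tissues[tissue_of],
                         status = status_of,
                         stringsAsFactors = FALSE)
  truth <- list(tissue_specific_sites = site_ids[ts_idx],
                signature_tissue = stats::setNames(cfg$tissues[sig_tissue],
                                                   site_ids[ts_idx]),
                disease_specific_sites = ds_sites,
                healthy_means = healthy_means,
                disease_means = disease_means)
  list(betas = methyl_matrix(betas), metadata = metadata, truth = truth)
}

#' Generate a null cohort with no planted effects
#'
#' Every site is identically distributed across tissues and statuses; all
#' samples are labelled healthy. Supports type-I-error testing of the
#' tissue-specificity screen.
#'
#' @param n_samples_per_tissue samples per tissue.
#' @param n_sites number of CpG sites.
#' @param tissues tissue labels.
#' @param seed integer seed.
#' @param dispersion beta-noise concentration.
#' @return list with \code{betas} and \code{metadata}.
#' @export
null_cohort <- function(n_samples_per_tissue, n_sites,
                        tissues = default_tissues(), seed = 1L,
                        dispersion = 50) {
  cfg <- cohort_config(tissues = tissues,
                       n_healthy_per_tissue = n_samples_per_tissue,
                       n_disease_per_tissue = 0,
                       n_sites = n_sites,
                       n_tissue_specific = 0,
                       n_disease_specific_per_tissue = 0,
                       dispersion = dispersion,
                       seed = seed)
  out <- generate_cohort(cfg)
  list(betas = out$betas, metadata = out$metadata)
}

#' Generate a cohort whose label depends on a two-site interaction
#'
#' Two designated sites a and b each carry a latent binary methylation state
#' (low mean \code{mu_low} or high mean \code{mu_high}); the disease label is
#' the exclusive-or of the two states, so neither site is marginally
#' informative and a linear model sees no signal. The remaining sites are
#' pure noise. This is the stress case for comparing the gated-residual
#' classifier against its no-residual baseline: the label is reachable only
#' through a nonlinear interaction.
#'
#' @param n_per_class samples per class (healthy/disease).
#' @param n_sites total sites (>= 2); sites 1 and 2 are the interacting pair.
#' @param seed integer seed.
#' @param mu_low,mu_high the two latent state means (defaults 0.25, 0.75).
#' @param dispersion beta-noise concentration.
#' @param tissue tissue label for the metadata.
#' @return list with \code{betas}, \code{metadata}, and
#'   \code{interacting_sites}.
#' @export
interaction_cohort <- function(n_per_class, n_sites, seed = 1L,
                               mu_low = 0.25, mu_high = 0.75,
                               dispersion = 50, tissue = "brain") {
  stopifnot(n_sites >= 2, n_per_class >= 2)
  set.seed(sub_seed(seed, 11))
  n <- 2L * n_per_class
  # balanced latent states: label 0 <- (0,0) or (1,1); label 1 <- (0,1) or (1,0)
  half <- function(k) rep_len(c(0L, 1L), k)
  za <- c(half(n_per_class), half(n_per_class))
  zb <- c(half(n_per_class), 1L - half(n_per_class))
  status <- rep(c(0L, 1L), each = n_per_class)
  ord <- sample.int(n)
  za <- za[ord]; zb <- zb[ord]; status <- status[ord]

  site_ids <- sprintf("cg%08d", seq_len(n_sites))
  sample_ids <- sprintf("%s_s%04d", tissue, seq_len(n))
  base <- stats::runif(n_sites, 0.2, 0.8)
  betas <- matrix(NA_real_, n, n_sites,
                  dimnames = list(sample_ids, site_ids))
  for (i in seq_len(n)) {
    mu <- base
    mu[1L] <- if (za[i] == 1L) mu_high else mu_low
    mu[2L] <- if (zb[i] == 1L) mu_high else mu_low
    betas[i, ] <- draw_cells(mu, dispersion, "beta")
  }
  metadata <- data.frame(sample_id = sample_ids, tissue = tissue,
                         status = status, stringsAsFactors = FALSE)
  list(betas = methyl_matrix(betas), metadata = metadata,
       interacting_sites = site_ids[1:2])
}

#' Write a ground-truth manifest as a long table
#'
#' @param truth the \code{truth} element of \code{\link{generate_cohort}}.
#' @return data.frame with columns site_id, category, tissue, healthy_mean,
#'   disease_mean.
#' @export
ground_truth_table <- function(truth) {
  rows <- list()
  for (s in truth$tissue_specific_sites) {
    t <- truth$signature_tissue[[s]]
    dis <- s %in% truth$disease_specific_sites[[t]]
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = s,
      category = if (dis) "tissue_and_disease" else "tissue_specific",
      tissue = t,
      healthy_mean = truth$healthy_means[s, t],
      disease_mean = truth$disease_means[s, t],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(site_id = character(0), category = character(0),
                      tissue = character(0), healthy_mean = numeric(0),
                      disease_mean = numeric(0)))
  do.call(rbind, rows)
}
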
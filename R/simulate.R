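# All generators are pure functions of their parameter objects: the RNG state
# is saved, seeded from params$seed, and restored on exit.
local_seed <- function(seed) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  set.seed(as.integer(seed))
  restore <- function() {
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }
  restore
}

# mean/dispersion negative binomial: variance mu + phi mu^2
rnbinom_mu <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, size = 1 / phi, mu = mu)
}

#' Parameters for the two-subtype bulk RNA-seq simulator
#'
#' Defaults mirror the design of the discovery cohort: 28 LAR and 95 non-LAR
#' tumors, an androgen-receptor anchor gene with a correlated module, and a
#' planted set of strongly differentially expressed genes on top of
#' negative-binomial noise. `n_genes` defaults to 2000 (not the full
#' transcriptome) so that a default simulation runs in well under a second;
#' module and DE set sizes keep the published proportions of the gene space.
#'
#' @param n_lar,n_nonlar samples per subtype.
#' @param n_genes total genes simulated.
#' @param anchor_gene symbol given to the anchor gene.
#' @param module_size genes sharing the anchor's latent factor.
#' @param module_correlation target latent-scale correlation, in (0,1).
#' @param n_de_genes genes planted with a subtype effect.
#' @param log2fc_magnitude absolute planted log2 fold change.
#' @param nb_dispersion negative-binomial dispersion phi (variance mu+phi*mu^2).
#' @param library_size_range relative library-size factors, sampled uniformly.
#' @param latent_sd scale of the shared latent factor on the log2-mean scale.
#' @param seed RNG seed.
#' @return list of class `bulk_sim_params`.
#' @export
bulk_sim_params <- function(n_lar = 28, n_nonlar = 95, n_genes = 2000,
                            anchor_gene = "AR", module_size = 130,
                            module_correlation = 0.9, n_de_genes = 52,
                            log2fc_magnitude = 3, nb_dispersion = 0.2,
                            library_size_range = c(0.7, 1.3),
                            latent_sd = 1, seed = 1) {
  p <- list(n_lar = n_lar, n_nonlar = n_nonlar, n_genes = n_genes,
            anchor_gene = anchor_gene, module_size = module_size,
            module_correlation = module_correlation, n_de_genes = n_de_genes,
            log2fc_magnitude = log2fc_magnitude, nb_dispersion = nb_dispersion,
            library_size_range = library_size_range, latent_sd = latent_sd,
            seed = seed)
  stopifnot(n_lar >= 2, n_nonlar >= 2, n_genes >= 3,
            module_size >= 0, n_de_genes >= 0,
            module_size + n_de_genes + 1 <= n_genes,
            module_correlation > 0, module_correlation < 1,
            nb_dispersion >= 0, latent_sd >= 0)
  class(p) <- "bulk_sim_params"
  p
}

#' Simulate a two-subtype bulk RNA-seq count cohort
#'
#' Gene base means are log-normal; an anchor gene and `module_size` module
#' genes share a per-sample latent factor on the log2-mean scale (module genes
#' load on it at `module_correlation`, plus independent residual so the
#' latent-scale correlation with the anchor equals the target); `n_de_genes`
#' further genes differ between the subtypes by `+/- log2fc_magnitude`. Counts
#' are negative binomial. The latent factor is shifted up in the LAR group so
#' the module tracks the subtype, as an androgen-receptor module does.
#'
#' @param params a [bulk_sim_params()].
#' @return list with `expr` (raw-count [expression_matrix()]), `samples`
#'   (a [sample_table()] with the true `group_label`) and `truth`
#'   (module genes, DE genes with signed planted log2 fold changes, latent
#'   factor).
#' @export
simulate_bulk <- function(params) {
  stopifnot(inherits(params, "bulk_sim_params"))
  restore <- local_seed(params$seed); on.exit(restore())
  p <- params
  n <- p$n_lar + p$n_nonlar
  group <- rep(c("LAR", "non-LAR"), c(p$n_lar, p$n_nonlar))
  genes <- sprintf("G%05d", seq_len(p$n_genes))
  genes[1L] <- p$anchor_gene
  module <- genes[1L + seq_len(p$module_size)]
  de <- genes[1L + p$module_size + seq_len(p$n_de_genes)]

  base_log2 <- stats::rnorm(p$n_genes, mean = log2(150), sd = 1.2)
  z <- stats::rnorm(n) + ifelse(group == "LAR", 1.5, 0)  # shared latent factor
  log2mu <- matrix(base_log2, p$n_genes, n)
  rho <- p$module_correlation
  log2mu[1L, ] <- log2mu[1L, ] + p$latent_sd * z
  if (p$module_size > 0) {
    eps <- matrix(stats::rnorm(p$module_size * n), p$module_size, n)
    load <- rho * matrix(z, p$module_size, n, byrow = TRUE) +
      sqrt(1 - rho^2) * eps
    log2mu[1L + seq_len(p$module_size), ] <-
      log2mu[1L + seq_len(p$module_size), ] + p$latent_sd * load
  }
  de_sign <- numeric(0)
  if (p$n_de_genes > 0) {
    de_sign <- rep_len(c(1, -1), p$n_de_genes)  # sign of non-LAR vs LAR effect
    idx <- 1L + p$module_size + seq_len(p$n_de_genes)
    shift <- outer(de_sign * p$log2fc_magnitude, as.numeric(group == "non-LAR"))
    log2mu[idx, ] <- log2mu[idx, ] + shift
  }
  size_factor <- stats::runif(n, p$library_size_range[1L],
                              p$library_size_range[2L])
  mu <- 2^log2mu * matrix(size_factor, p$n_genes, n, byrow = TRUE)
  counts <- matrix(rnbinom_mu(length(mu), mu, p$nb_dispersion),
                   p$n_genes, n,
                   dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  list(expr = expression_matrix(counts, "raw_counts"),
       samples = sample_table(colnames(counts), dataset_id = "sim",
                              group_label = group),
       truth = list(anchor_gene = p$anchor_gene, module_genes = module,
                    de_genes = de,
                    de_log2fc = stats::setNames(de_sign * p$log2fc_magnitude, de),
                    latent = z, size_factor = size_factor))
}

#' Parameters for the single-cell reference simulator
#'
#' Twenty cell types by default, matching the cell-type roster size of the
#' single-cell reference the deconvolution stage assumes. Dropout is logistic
#' in `log1p` of the pre-dropout mean: `p_drop = plogis(slope * (midpoint -
#' log1p(mu)))`, monotone non-increasing in the mean for `slope >= 0`.
#'
#' @param n_types number of cell types (>= 2).
#' @param cells_per_type cells simulated per type.
#' @param n_genes genes simulated.
#' @param type_profile_separation sd of per-type log2 profile shifts.
#' @param dropout_midpoint,dropout_slope logistic dropout curve parameters.
#' @param nb_dispersion per-cell count dispersion.
#' @param seed RNG seed.
#' @return list of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_types = 20, cells_per_type = 120, n_genes = 2000,
                          type_profile_separation = 1,
                          dropout_midpoint = 1, dropout_slope = 1,
                          nb_dispersion = 0.4, seed = 1) {
  stopifnot(n_types >= 2, cells_per_type >= 2, n_genes >= 2,
            type_profile_separation >= 0, dropout_slope >= 0,
            nb_dispersion >= 0)
  structure(list(n_types = n_types, cells_per_type = cells_per_type,
                 n_genes = n_genes,
                 type_profile_separation = type_profile_separation,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 nb_dispersion = nb_dispersion, seed = seed),
            class = "sc_sim_params")
}

#' Simulate a typed single-cell count matrix with dropout and an embedding
#'
#' Each type has its own log-normal expression profile (base means shifted per
#' type by `type_profile_separation`); cells draw negative-binomial counts
#' around their type profile, then zeros are inflated by independent Bernoulli
#' thinning with the logistic mean-dropout curve. The returned 2-D embedding
#' places each type in its own unit-sd Gaussian blob on a circle whose radius
#' scales with the profile separation (a stand-in for a t-SNE layout; the
#' package consumes embeddings, it does not compute them).
#'
#' @param params an [sc_sim_params()].
#' @return list with `expr` (cells as columns, raw counts), `cell_types`
#'   (factor), `embedding` (cells x 2 matrix) and `truth` (type profiles,
#'   pre-dropout means, dropout probabilities).
#' @export
simulate_single_cell <- function(params) {
  stopifnot(inherits(params, "sc_sim_params"))
  restore <- local_seed(params$seed); on.exit(restore())
  p <- params
  n_cells <- p$n_types * p$cells_per_type
  types <- paste0("T", seq_len(p$n_types))
  cell_type <- factor(rep(types, each = p$cells_per_type), levels = types)
  genes <- sprintf("G%05d", seq_len(p$n_genes))

  base_log2 <- stats::rnorm(p$n_genes, mean = log2(20), sd = 1.5)
  profile_log2 <- base_log2 +
    matrix(stats::rnorm(p$n_genes * p$n_types, sd = p$type_profile_separation),
           p$n_genes, p$n_types, dimnames = list(genes, types))
  size_factor <- stats::runif(n_cells, 0.5, 1.5)
  mu <- 2^profile_log2[, as.integer(cell_type), drop = FALSE] *
    matrix(size_factor, p$n_genes, n_cells, byrow = TRUE)
  counts <- matrix(rnbinom_mu(length(mu), mu, p$nb_dispersion),
                   p$n_genes, n_cells)
  p_drop <- stats::plogis(p$dropout_slope * (p$dropout_midpoint - log1p(mu)))
  keep <- matrix(stats::rbinom(length(mu), 1L, 1 - p_drop),
                 p$n_genes, n_cells)
  counts <- counts * keep
  dimnames(counts) <- list(genes, sprintf("C%05d", seq_len(n_cells)))

  centers <- 20 * p$type_profile_separation *
    cbind(cos(2 * pi * seq_len(p$n_types) / p$n_types),
          sin(2 * pi * seq_len(p$n_types) / p$n_types))
  embedding <- centers[as.integer(cell_type), , drop = FALSE] +
    matrix(stats::rnorm(2 * n_cells), n_cells, 2)
  dimnames(embedding) <- list(colnames(counts), c("dim1", "dim2"))

  list(expr = expression_matrix(counts, "raw_counts"),
       cell_types = stats::setNames(cell_type, colnames(counts)),
       embedding = embedding,
       truth = list(profile_log2 = profile_log2, mu = mu, p_drop = p_drop,
                    size_factor = size_factor))
}

#' Simulate pseudo-bulk mixtures with known cell-type fractions
#'
#' Each pseudo-bulk sample is the fraction-weighted average of the per-type
#' mean profiles of the reference cells (computed on the counts-per-10k scale,
#' so cell library depth does not leak into the profiles) plus i.i.d. Gaussian
#' noise, truncated at zero.
#'
#' @param reference_cells raw-count [expression_matrix()], cells as columns.
#' @param labels cell-type label per reference cell.
#' @param fractions samples x cell-types matrix; rows must be non-negative and
#'   sum to 1; column names must be reference types.
#' @param noise_sd sd of additive Gaussian noise.
#' @param seed RNG seed.
#' @return list with `bulk` (genes x samples [expression_matrix()], kind
#'   `scaled`) and `profiles` (genes x types matrix actually mixed).
#' @export
simulate_mixtures <- function(reference_cells, labels, fractions,
                              noise_sd = 0, seed = 1) {
  restore <- local_seed(seed); on.exit(restore())
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(reference_cells))
  fractions <- as.matrix(fractions)
  if (is.null(colnames(fractions))) stop("fractions need cell-type colnames")
  if (any(fractions < 0) || any(abs(rowSums(fractions) - 1) > 1e-8))
    stop("fraction rows must be non-negative and sum to 1")
  missing_types <- setdiff(colnames(fractions), unique(labels))
  if (length(missing_types))
    stop("no reference cells for type(s): ",
         paste(missing_types, collapse = ", "))
  cp10k <- t(t(as_plain(reference_cells)) /
               pmax(colSums(reference_cells), 1)) * 1e4
  profiles <- vapply(colnames(fractions), function(tp)
    rowMeans(cp10k[, labels == tp, drop = FALSE]),
    numeric(nrow(reference_cells)))
  bulk <- profiles %*% t(fractions)
  if (noise_sd > 0)
    bulk <- bulk + matrix(stats::rnorm(length(bulk), sd = noise_sd),
                          nrow(bulk), ncol(bulk))
  bulk <- pmax(bulk, 0)
  rownames(bulk) <- rownames(reference_cells)
  colnames(bulk) <- if (!is.null(rownames(fractions))) rownames(fractions)
    else sprintf("M%03d", seq_len(nrow(fractions)))
  list(bulk = expression_matrix(bulk, "scaled"), profiles = profiles)
}

#' Parameters for the multi-arm binary-outcome trial simulator
#'
#' Defaults emulate the pooled neoadjuvant-chemotherapy analysis: 13 arms,
#' small LAR groups (n = 15) against larger non-LAR groups (n = 75), a
#' baseline LAR pCR rate near 17% and a mean non-LAR odds ratio of 2.11, with
#' arm-level heterogeneity in both the baseline and the group effect.
#'
#' @param n_arms number of treatment arms.
#' @param n_lar,n_nonlar per-arm group sizes (scalars or length-`n_arms`).
#' @param baseline_logit_mean mean baseline logit `b0` (LAR log-odds of pCR).
#' @param baseline_logit_sd sd of the arm-level baseline random effect.
#' @param lar_effect_mean mean non-LAR log-odds-ratio `bL`.
#' @param lar_effect_sd sd of the arm-level effect random effect.
#' @param seed RNG seed.
#' @return list of class `trial_sim_params`.
#' @export
trial_sim_params <- function(n_arms = 13, n_lar = 15, n_nonlar = 75,
                             baseline_logit_mean = stats::qlogis(0.17),
                             baseline_logit_sd = 0.4,
                             lar_effect_mean = log(2.11),
                             lar_effect_sd = 0.2, seed = 1) {
  n_lar <- rep_len(n_lar, n_arms); n_nonlar <- rep_len(n_nonlar, n_arms)
  stopifnot(n_arms >= 1, all(n_lar >= 1), all(n_nonlar >= 1),
            baseline_logit_sd >= 0, lar_effect_sd >= 0)
  structure(list(n_arms = n_arms, n_lar = n_lar, n_nonlar = n_nonlar,
                 baseline_logit_mean = baseline_logit_mean,
                 baseline_logit_sd = baseline_logit_sd,
                 lar_effect_mean = lar_effect_mean,
                 lar_effect_sd = lar_effect_sd, seed = seed),
            class = "trial_sim_params")
}

#' Simulate arm-level 2x2 pCR tables under the random-effects logit model
#'
#' Per arm i: `p_LAR = plogis(b0 + u_i)` and
#' `p_nonLAR = plogis(b0 + u_i + bL + v_i)` with independent
#' `u_i ~ N(0, sd_u^2)`, `v_i ~ N(0, sd_v^2)`; cell counts are binomial draws.
#' This is exactly the generative model [fit_random_effects_logit()] estimates.
#'
#' @param params a [trial_sim_params()].
#' @return list with `arms` (an `arm_table`) and `truth` (per-arm `u`, `v` and
#'   response probabilities).
#' @export
simulate_trials <- function(params) {
  stopifnot(inherits(params, "trial_sim_params"))
  restore <- local_seed(params$seed); on.exit(restore())
  p <- params
  u <- stats::rnorm(p$n_arms, 0, p$baseline_logit_sd)
  v <- stats::rnorm(p$n_arms, 0, p$lar_effect_sd)
  p_lar <- stats::plogis(p$baseline_logit_mean + u)
  p_non <- stats::plogis(p$baseline_logit_mean + u + p$lar_effect_mean + v)
  lar_yes <- stats::rbinom(p$n_arms, p$n_lar, p_lar)
  non_yes <- stats::rbinom(p$n_arms, p$n_nonlar, p_non)
  arms <- arm_table(data.frame(
    trial = sprintf("SIM%02d", seq_len(p$n_arms)), arm = "-",
    lar_yes = lar_yes, lar_no = p$n_lar - lar_yes,
    nonlar_yes = non_yes, nonlar_no = p$n_nonlar - non_yes))
  list(arms = arms,
       truth = list(u = u, v = v, p_lar = p_lar, p_nonlar = p_non))
}
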
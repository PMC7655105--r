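#' Specification for a simulated circadian time-course experiment
#'
#' Defaults emulate a constant-condition circadian sampling design: two
#' entrainment treatments, leaf sampling every 2 h for 48 h (ZT24-ZT70),
#' two biological replicates, a 24 h period, and negative-binomial counts
#' (variance mu + dispersion * mu^2). Genes belong to one of
#' \code{n_modules} phase modules with evenly spaced peak phases.
#' Perturbations (applied to the second treatment only) come in three
#' classes at weak/medium/strong intensity: phase shifts of 2/4/8 h,
#' amplitude scaling by 0.75/0.5/0.25, or loss of rhythm (arrhythmic).
#'
#' @param n_genes number of genes.
#' @param n_modules number of phase modules.
#' @param n_perturbed number of genes perturbed in treatment 2.
#' @param perturb_classes class names drawn for perturbed genes.
#' @param time_start,time_step,n_times sampling grid in hours.
#' @param treatments character vector of length 2.
#' @param replicates number of replicate courses per treatment.
#' @param period rhythm period tau (hours).
#' @param baseline_logmean,baseline_logsd log-normal baseline abundance.
#' @param amp_range relative-amplitude range (uniform draw).
#' @param phase_jitter_sd within-module phase jitter SD (hours).
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param paired if TRUE (default) unperturbed genes keep the same module,
#'   phase and amplitude in both treatments; if FALSE those pattern
#'   attributes are redrawn independently for the second treatment,
#'   generating data under the pattern test's null hypothesis that gene
#'   identity carries no cross-treatment pattern information (used for
#'   type-I calibration).
#' @param seed integer seed.
#' @return list of class \code{sim_spec}.
#' @export
sim_spec <- function(n_genes = 10000L, n_modules = 12L, n_perturbed = 1200L,
                     perturb_classes = c("phase_shift", "amplitude_change",
                                         "arrhythmic"),
                     time_start = 24, time_step = 2, n_times = 24L,
                     treatments = c("LD", "HC"), replicates = 2L,
                     period = 24, baseline_logmean = 4, baseline_logsd = 1.2,
                     amp_range = c(0.3, 1), phase_jitter_sd = 0.75,
                     dispersion = 0.05, paired = TRUE, seed = 1L) {
  if (n_perturbed > n_genes) stop("n_perturbed cannot exceed n_genes")
  if (length(treatments) != 2) stop("exactly 2 treatments are supported")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(as.list(environment()), class = "sim_spec")
}

## perturbation intensity grids: weak/medium/strong
.shift_hours <- c(weak = 2, medium = 4, strong = 8)
.amp_factors <- c(weak = 0.75, medium = 0.5, strong = 0.25)

#' Simulate a two-treatment circadian time course with known truth
#'
#' Mean model \eqn{\mu_g(t) = e^{b_g}(1 + A_g\cos(2\pi(t-\varphi_g)/\tau))}
#' clipped at 0; counts are negative binomial with per-sample depth
#' factors. Treatment-2 curves are modified for perturbed genes according
#' to their class and intensity.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return list with \code{counts} (a \code{count_table}), \code{design}
#'   (a \code{sample_design}), \code{truth} (per-gene data.frame: module,
#'   class, intensity, delta_phase, amp_factor, perturbed, plus the drawn
#'   baseline/amplitude/phase parameters), and \code{depth_factors}
#'   (per-sample sequencing-depth multipliers).
#' @export
simulate_timecourse <- function(spec) {
  with_seed(spec$seed, {
    g <- spec$n_genes
    times <- spec$time_start + spec$time_step * (seq_len(spec$n_times) - 1)
    design <- expand.grid(time = times,
                          replicate = paste0("rep", seq_len(spec$replicates)),
                          treatment = spec$treatments,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_ZT%02d_%s", design$treatment, as.integer(design$time),
                             design$replicate)
    design <- sample_design(design[c("sample", "treatment", "time",
                                     "replicate")])
    module <- sample.int(spec$n_modules, g, replace = TRUE)
    mod_phase <- (module - 1) * spec$period / spec$n_modules
    phase <- (mod_phase + stats::rnorm(g, 0, spec$phase_jitter_sd)) %% spec$period
    base <- exp(stats::rnorm(g, spec$baseline_logmean, spec$baseline_logsd))
    amp <- stats::runif(g, spec$amp_range[1], spec$amp_range[2])
    lens <- round(stats::runif(g, 500, 5000))
    ids <- sprintf("gene%05d", seq_len(g))
    perturbed <- rep(FALSE, g)
    cls <- rep("none", g); intensity <- rep(NA_character_, g)
    dphi <- rep(0, g); afac <- rep(1, g)
    if (spec$n_perturbed > 0) {
      idx <- sample.int(g, spec$n_perturbed)
      perturbed[idx] <- TRUE
      cls[idx] <- sample(spec$perturb_classes, spec$n_perturbed, replace = TRUE)
      intensity[idx] <- sample(c("weak", "medium", "strong"),
                               spec$n_perturbed, replace = TRUE)
      is_shift <- cls == "phase_shift"
      dphi[is_shift] <- .shift_hours[intensity[is_shift]]
      is_amp <- cls == "amplitude_change"
      afac[is_amp] <- .amp_factors[intensity[is_amp]]
      afac[cls == "arrhythmic"] <- 0
    }
    ## second-treatment pattern attributes: inherited (paired) or redrawn
    ## under the test's cross-treatment-independence null
    if (isTRUE(spec$paired %||% TRUE)) {
      phase_t2 <- (phase + dphi) %% spec$period
      amp_t2 <- amp * afac
    } else {
      module2 <- sample.int(spec$n_modules, g, replace = TRUE)
      phase_t2 <- ((module2 - 1) * spec$period / spec$n_modules +
                     stats::rnorm(g, 0, spec$phase_jitter_sd)) %% spec$period
      amp_t2 <- stats::runif(g, spec$amp_range[1], spec$amp_range[2])
    }
    depth <- exp(stats::rnorm(nrow(design), 0, 0.1))
    counts <- matrix(0L, g, nrow(design),
                     dimnames = list(ids, design$sample))
    trt2 <- design$treatment == spec$treatments[2]
    for (s in seq_len(nrow(design))) {
      t <- design$time[s]
      ph <- phase; a <- amp
      if (trt2[s]) {
        ph <- phase_t2
        a <- amp_t2
      }
      mu <- base * pmax(0, 1 + a * cos(2 * pi * (t - ph) / spec$period))
      mu_s <- mu * (lens / 1000) * depth[s]
      counts[, s] <- if (spec$dispersion > 0)
        stats::rnbinom(g, mu = mu_s, size = 1 / spec$dispersion)
      else stats::rpois(g, mu_s)
    }
    truth <- data.frame(gene = ids, module = module, class = cls,
                        intensity = intensity, delta_phase = dphi,
                        amp_factor = afac, perturbed = perturbed,
                        baseline = base, amplitude = amp, phase = phase,
                        phase_t2 = phase_t2, amplitude_t2 = amp_t2,
                        length_bp = lens, stringsAsFactors = FALSE)
    list(counts = count_table(counts, stats::setNames(lens, ids)),
         design = design, truth = truth,
         depth_factors = stats::setNames(depth, design$sample))
  })
}

#' Simulate paralog pairs with controlled pattern divergence
#'
#' Pairs share a baseline and amplitude; a stated fraction of pairs are
#' antiphase (the second member's phase is shifted by half a period), the
#' rest share the first member's phase. Responsiveness flags for
#' enrichment-test calibration are assigned either independently of
#' divergence or coupled to it (exactly one member of a divergent pair is
#' preferentially responsive).
#'
#' @param n_pairs number of pairs.
#' @param antiphase_frac fraction of pairs made antiphase.
#' @param responsive_rule "independent" or "coupled".
#' @param responsive_prob marginal per-gene responsiveness probability
#'   under the independent rule (default 0.3).
#' @param coupled_prob probability that a divergent pair has exactly one
#'   responsive member under the coupled rule (default 0.8).
#' @param spec a \code{\link{sim_spec}} supplying the design and noise
#'   parameters (its n_genes/n_perturbed fields are ignored).
#' @param seed integer seed.
#' @return list with \code{counts}, \code{design}, \code{pairs} (group_id,
#'   gene1, gene2), \code{truth} (pair-level: antiphase flag), and
#'   \code{responsive} (character vector of responsive gene ids).
#' @export
simulate_paralog_pairs <- function(n_pairs = 500L, antiphase_frac = 0.2,
                                   responsive_rule = c("independent",
                                                       "coupled"),
                                   responsive_prob = 0.3, coupled_prob = 0.8,
                                   spec = sim_spec(), seed = 1L) {
  responsive_rule <- match.arg(responsive_rule)
  if (antiphase_frac < 0 || antiphase_frac > 1)
    stop("antiphase_frac must be in [0, 1]")
  with_seed(seed, {
    n_anti <- round(n_pairs * antiphase_frac)
    anti <- c(rep(TRUE, n_anti), rep(FALSE, n_pairs - n_anti))
    times <- spec$time_start + spec$time_step * (seq_len(spec$n_times) - 1)
    design <- expand.grid(time = times,
                          replicate = paste0("rep", seq_len(spec$replicates)),
                          treatment = spec$treatments,
                          stringsAsFactors = FALSE)
    design$sample <- sprintf("%s_ZT%02d_%s", design$treatment, as.integer(design$time),
                             design$replicate)
    design <- sample_design(design[c("sample", "treatment", "time",
                                     "replicate")])
    base <- exp(stats::rnorm(n_pairs, spec$baseline_logmean,
                             spec$baseline_logsd))
    amp <- stats::runif(n_pairs, spec$amp_range[1], spec$amp_range[2])
    phase <- stats::runif(n_pairs, 0, spec$period)
    g1 <- sprintf("pair%04d_a", seq_len(n_pairs))
    g2 <- sprintf("pair%04d_b", seq_len(n_pairs))
    ids <- c(g1, g2)
    phase2 <- ifelse(anti, (phase + spec$period / 2) %% spec$period, phase)
    lens <- round(stats::runif(2 * n_pairs, 500, 5000))
    depth <- exp(stats::rnorm(nrow(design), 0, 0.1))
    counts <- matrix(0L, 2 * n_pairs, nrow(design),
                     dimnames = list(ids, design$sample))
    for (s in seq_len(nrow(design))) {
      t <- design$time[s]
      mu <- c(base * pmax(0, 1 + amp * cos(2 * pi * (t - phase) / spec$period)),
              base * pmax(0, 1 + amp * cos(2 * pi * (t - phase2) / spec$period)))
      mu_s <- mu * (lens / 1000) * depth[s]
      counts[, s] <- if (spec$dispersion > 0)
        stats::rnbinom(length(mu_s), mu = mu_s, size = 1 / spec$dispersion)
      else stats::rpois(length(mu_s), mu_s)
    }
    responsive <- if (responsive_rule == "independent") {
      ids[stats::runif(2 * n_pairs) < responsive_prob]
    } else {
      ## coupled: divergent pairs preferentially have exactly one
      ## responsive member; background rate elsewhere
      resp <- character(0)
      one <- anti & stats::runif(n_pairs) < coupled_prob
      pick1 <- stats::runif(n_pairs) < 0.5
      resp <- c(resp, ifelse(pick1, g1, g2)[one])
      bg <- stats::runif(2 * n_pairs) < responsive_prob / 3
      members <- ids[bg]
      unique(c(resp, members))
    }
    pairs <- data.frame(group_id = sprintf("pg%04d", seq_len(n_pairs)),
                        gene1 = g1, gene2 = g2, stringsAsFactors = FALSE)
    truth <- data.frame(group_id = pairs$group_id, antiphase = anti,
                        phase1 = phase, phase2 = phase2,
                        stringsAsFactors = FALSE)
    list(counts = count_table(counts, stats::setNames(lens, ids)),
         design = design, pairs = pairs, truth = truth,
         responsive = responsive)
  })
}

#' Simulate a two-species gene regulatory network with paralog divergence
#'
#' Species A has \code{n_tf} transcription factors with smooth rhythmic
#' profiles and \code{n_targets} targets, each a linear mix of its
#' regulators plus noise. Species B duplicates every TF: the conserved copy
#' drives the orthologs of the A targets; the divergent copy drives a
#' target set with a fraction \code{divergence_frac} rewired to random
#' other targets.
#'
#' @param n_tf,n_targets network dimensions.
#' @param edges_per_target true regulators per target (1 or 2 typical).
#' @param noise_sd target noise SD relative to unit-variance signals.
#' @param divergence_frac fraction of the divergent copy's targets rewired.
#' @param n_samples expression samples per species (default 48).
#' @param seed integer seed.
#' @return list with \code{es_a}, \code{es_b} (expression sets),
#'   \code{tf_a}, \code{tf_b} (TF id vectors), \code{targets_a},
#'   \code{targets_b}, \code{true_edges_a}, \code{true_edges_b}
#'   (data.frames tf, target), \code{ortholog_map} (br, at),
#'   \code{triplets} (at_tf, br_copy_a, br_copy_b).
#' @export
simulate_grn <- function(n_tf = 10L, n_targets = 100L, edges_per_target = 2L,
                         noise_sd = 0.3, divergence_frac = 1,
                         n_samples = 48L, seed = 1L) {
  if (min(n_tf, n_targets, edges_per_target, n_samples) < 1 || noise_sd < 0)
    stop("all parameters must be positive")
  if (divergence_frac < 0 || divergence_frac > 1)
    stop("divergence_frac must be in [0, 1]")
  with_seed(seed, {
    times <- seq(0, by = 2, length.out = n_samples)
    ## random smooth rhythm: random Fourier series (fundamental plus two
    ## harmonics) with an equally weighted smooth idiosyncratic component
    ## (moving-average filtered noise), so distinct TFs share the clock but
    ## are far from collinear
    smooth_rhythm <- function() {
      y <- rep(0, n_samples)
      for (k in 1:3) {
        w <- 2 * pi * k * times / 24
        y <- y + stats::rnorm(1, 0, 1 / k) * cos(w) +
          stats::rnorm(1, 0, 1 / k) * sin(w)
      }
      idio <- stats::filter(stats::rnorm(n_samples + 4), rep(1 / 3, 3),
                            sides = 2)
      idio <- as.numeric(idio[3:(n_samples + 2)])
      y <- as.numeric(scale(y)) + as.numeric(scale(idio))
      as.numeric(scale(y))
    }
    tf_a <- sprintf("AtTF%02d", seq_len(n_tf))
    targets_a <- sprintf("AtG%03d", seq_len(n_targets))
    prof_tf_a <- t(vapply(tf_a, function(i) smooth_rhythm(),
                          numeric(n_samples)))
    reg <- lapply(seq_len(n_targets), function(j)
      sample.int(n_tf, edges_per_target))
    coefs <- lapply(seq_len(n_targets), function(j)
      stats::runif(edges_per_target, 0.7, 1.3) *
        sample(c(-1, 1), edges_per_target, replace = TRUE))
    mix <- function(proftf, regs, cf) {
      y <- drop(cf %*% proftf[regs, , drop = FALSE]) +
        stats::rnorm(n_samples, 0, noise_sd)
      as.numeric(scale(y))
    }
    prof_tg_a <- t(mapply(function(r, cf) mix(prof_tf_a, r, cf), reg, coefs))
    rownames(prof_tg_a) <- targets_a
    ## species B: conserved + divergent copy per TF
    copy_a <- sprintf("BrTF%02da", seq_len(n_tf))
    copy_b <- sprintf("BrTF%02db", seq_len(n_tf))
    targets_b <- sprintf("BrG%03d", seq_len(n_targets))
    prof_ca <- t(vapply(copy_a, function(i) smooth_rhythm(),
                        numeric(n_samples)))
    prof_cb <- t(vapply(copy_b, function(i) smooth_rhythm(),
                        numeric(n_samples)))
    ## species-B topology: the conserved copy inherits the orthologous
    ## out-edges; the divergent copy keeps (1 - divergence_frac) of them
    ## and rewires the rest to random other targets. Each B target is then
    ## mixed in a single pass from all of its drivers so conserved and
    ## divergent edges carry comparable signal.
    out_sets_a <- lapply(seq_len(n_tf), function(i)
      which(vapply(reg, function(r) i %in% r, TRUE)))
    drivers_b <- lapply(seq_len(n_targets), function(j)
      match(copy_a[reg[[j]]], c(copy_a, copy_b)))
    edges_b_div <- list()
    for (i in seq_len(n_tf)) {
      own <- out_sets_a[[i]]
      if (!length(own)) next
      n_rew <- round(divergence_frac * length(own))
      keep <- if (n_rew < length(own))
        sample(own, length(own) - n_rew) else integer(0)
      pool <- setdiff(seq_len(n_targets), own)
      rew <- if (n_rew > 0) sample(pool, min(n_rew, length(pool)))
             else integer(0)
      tg <- c(keep, rew)
      for (j in tg)
        drivers_b[[j]] <- c(drivers_b[[j]], n_tf + i)
      edges_b_div[[i]] <- data.frame(tf = copy_b[i], target = targets_b[tg],
                                     stringsAsFactors = FALSE)
    }
    prof_copies <- rbind(prof_ca, prof_cb)
    prof_tg_b <- t(vapply(seq_len(n_targets), function(j) {
      dr <- drivers_b[[j]]
      cf <- stats::runif(length(dr), 0.7, 1.3) *
        sample(c(-1, 1), length(dr), replace = TRUE)
      mix(prof_copies, dr, cf)
    }, numeric(n_samples)))
    rownames(prof_tg_b) <- targets_b
    true_edges_a <- do.call(rbind, lapply(seq_len(n_targets), function(j)
      data.frame(tf = tf_a[reg[[j]]], target = targets_a[j],
                 stringsAsFactors = FALSE)))
    true_edges_b <- rbind(
      do.call(rbind, lapply(seq_len(n_targets), function(j)
        data.frame(tf = copy_a[reg[[j]]], target = targets_b[j],
                   stringsAsFactors = FALSE))),
      do.call(rbind, edges_b_div))
    mk_es <- function(proftf, proftg, tfs, tgs) {
      mat <- rbind(proftf, proftg)
      rownames(mat) <- c(tfs, tgs)
      colnames(mat) <- sprintf("s%02d", seq_len(n_samples))
      des <- sample_design(colnames(mat), treatment = "sim", time = times,
                           replicate = "rep1")
      expression_set(mat, des)
    }
    list(es_a = mk_es(prof_tf_a, prof_tg_a, tf_a, targets_a),
         es_b = mk_es(rbind(prof_ca, prof_cb), prof_tg_b,
                      c(copy_a, copy_b), targets_b),
         tf_a = tf_a, tf_b = c(copy_a, copy_b),
         targets_a = targets_a, targets_b = targets_b,
         true_edges_a = true_edges_a, true_edges_b = true_edges_b,
         ortholog_map = data.frame(br = targets_b, at = targets_a,
                                   stringsAsFactors = FALSE),
         triplets = data.frame(at_tf = tf_a, br_copy_a = copy_a,
                               br_copy_b = copy_b, stringsAsFactors = FALSE))
  })
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midranks for ties; invariant under strictly monotone score transforms.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param truth_labels logical or 0/1 vector.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, truth_labels) {
  y <- as.logical(truth_labels)
  if (length(y) != length(scores)) stop("scores and labels differ in length")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
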
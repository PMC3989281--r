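#' Simulation specification for run-level oocyte count data
#'
#' Builds and validates the parameter set for [generate_counts()]. The
#' defaults reproduce the design of the sequencing experiment the package
#' analyses: two treatment groups (in vivo matured, IVV, and in vitro
#' matured, IVM), three biological replicates per group (pools of 10
#' oocytes), and two technical sequencing runs per replicate, with run
#' depths varying by a multiplicative library-size factor.
#'
#' Counts are drawn from a negative-binomial model with a shared dispersion:
#' transcript baseline means are log-normal, planted differential transcripts
#' get a true fold change (randomly signed between groups), and one labelled
#' marker transcript is simulated at sub-read abundance to emulate a
#' cumulus-cell contamination marker that should stay undetected.
#'
#' @param n_transcripts number of transcripts (the marker is one of them).
#' @param n_replicates_per_group biological replicates per group.
#' @param n_runs_per_replicate technical sequencing runs per replicate.
#' @param baseline_mean_log_mu,baseline_mean_log_sigma meanlog/sdlog of the
#'   log-normal distribution of per-transcript expected counts.
#' @param dispersion negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 degenerates to Poisson.
#' @param library_size_range length-2 interval of multiplicative run-depth
#'   factors, each > 0.
#' @param de_fraction proportion of transcripts given a true fold change.
#' @param fold_change_set candidate true fold changes, each >= 1.
#' @param marker_id identifier of the planted contamination-marker transcript.
#' @param marker_mean expected count of the marker (kept below one read).
#' @param seed integer seed; fully determines the output.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n_transcripts = 1000L,
                     n_replicates_per_group = 3L,
                     n_runs_per_replicate = 2L,
                     baseline_mean_log_mu = log(50),
                     baseline_mean_log_sigma = 1.5,
                     dispersion = 0.05,
                     library_size_range = c(0.7, 1.3),
                     de_fraction = 0.1,
                     fold_change_set = c(2, 4, 8),
                     marker_id = "CYP19A1",
                     marker_mean = 0.3,
                     seed = 1L) {
  n_transcripts <- check_count(n_transcripts, "n_transcripts")
  n_replicates_per_group <- check_count(n_replicates_per_group,
                                        "n_replicates_per_group")
  n_runs_per_replicate <- check_count(n_runs_per_replicate,
                                      "n_runs_per_replicate")
  check_number(baseline_mean_log_mu, "baseline_mean_log_mu")
  check_number(baseline_mean_log_sigma, "baseline_mean_log_sigma", lower = 0)
  check_number(dispersion, "dispersion", lower = 0)
  if (length(library_size_range) != 2L) {
    stop_validation("'library_size_range' must be a length-2 interval")
  }
  check_number(library_size_range, "library_size_range",
               lower = .Machine$double.eps, allow_zero_len = TRUE)
  if (library_size_range[1] > library_size_range[2]) {
    stop_validation("'library_size_range' must be ordered low, high")
  }
  check_number(de_fraction, "de_fraction", lower = 0, upper = 1)
  if (length(fold_change_set) < 1L) {
    stop_validation("'fold_change_set' must be non-empty")
  }
  check_number(fold_change_set, "fold_change_set", lower = 1,
               allow_zero_len = TRUE)
  check_number(marker_mean, "marker_mean", lower = 0)
  seed <- check_count(seed, "seed", lower = -.Machine$integer.max)
  structure(list(
    n_transcripts = n_transcripts,
    n_replicates_per_group = n_replicates_per_group,
    n_runs_per_replicate = n_runs_per_replicate,
    baseline_mean_log_mu = baseline_mean_log_mu,
    baseline_mean_log_sigma = baseline_mean_log_sigma,
    dispersion = dispersion,
    library_size_range = library_size_range,
    de_fraction = de_fraction,
    fold_change_set = fold_change_set,
    marker_id = as.character(marker_id),
    marker_mean = marker_mean,
    seed = seed
  ), class = "sim_spec")
}

# one NB/Poisson draw per element of mu
draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
}

#' Generate run-level transcript counts with known ground truth
#'
#' Draws one count table per (group, biological replicate, technical run).
#' Each run gets its own library-size factor, so run totals differ the way
#' real sequencing depths do; the normalization step is expected to undo
#' this. Planted differential transcripts have the expected count in the
#' higher group equal to fold times the expected count in the other group,
#' with the higher group chosen by a fair coin. Technical runs are
#' independent draws at run-specific depth, not a split of one draw.
#'
#' @param spec a [sim_spec()] object.
#' @param groups character vector of the two group labels.
#' @return A list with elements `runs` (a `run_counts` object: integer count
#'   matrix transcripts x runs plus a run manifest) and `truth` (a data frame
#'   of planted transcripts: id, fold change, higher group, baseline mean).
#' @export
generate_counts <- function(spec, groups = c("IVV", "IVM")) {
  if (!inherits(spec, "sim_spec")) spec <- do.call(sim_spec, spec)
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stop_validation("'groups' must be two distinct labels")
  }
  withr::with_seed(spec$seed, {
    n <- spec$n_transcripts
    ids <- sprintf("T%05d", seq_len(n))
    marker_idx <- n  # marker occupies the last row
    ids[marker_idx] <- spec$marker_id

    base_mean <- stats::rlnorm(n, spec$baseline_mean_log_mu,
                               spec$baseline_mean_log_sigma)
    base_mean[marker_idx] <- spec$marker_mean

    n_de <- round(spec$de_fraction * (n - 1L))
    eligible <- setdiff(seq_len(n), marker_idx)
    de_idx <- if (n_de > 0) {
      eligible[sample.int(length(eligible), n_de)]
    } else integer(0)
    fold <- rep(1, n)
    higher <- rep(NA_character_, n)
    if (n_de > 0) {
      fold[de_idx] <- spec$fold_change_set[
        sample.int(length(spec$fold_change_set), n_de, replace = TRUE)]
      higher[de_idx] <- groups[sample.int(2L, n_de, replace = TRUE)]
    }
    mu <- cbind(base_mean, base_mean)
    colnames(mu) <- groups
    for (g in groups) {
      up <- which(higher == g)
      mu[up, g] <- mu[up, g] * fold[up]
    }

    reps <- seq_len(spec$n_replicates_per_group)
    runs <- seq_len(spec$n_runs_per_replicate)
    manifest <- expand.grid(run = runs, replicate = reps, group = groups,
                            stringsAsFactors = FALSE)
    manifest$sample_id <- paste0(manifest$group, "_", manifest$replicate)
    manifest$run_id <- paste0(manifest$sample_id, "_run", manifest$run)
    lib <- stats::runif(nrow(manifest), spec$library_size_range[1],
                        spec$library_size_range[2])
    counts <- vapply(seq_len(nrow(manifest)), function(i) {
      as.numeric(draw_counts(mu[, manifest$group[i]] * lib[i],
                             spec$dispersion))
    }, numeric(n))
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(ids, manifest$run_id)

    truth <- data.frame(
      transcript_id = ids[de_idx],
      fold_change = fold[de_idx],
      higher_in = higher[de_idx],
      base_mean = base_mean[de_idx],
      stringsAsFactors = FALSE
    )
    list(
      runs = run_counts(counts,
                        manifest[, c("run_id", "sample_id", "group")]),
      truth = truth[order(truth$transcript_id), , drop = FALSE]
    )
  })
}

#' Generate a triplicate-well qPCR Ct plate
#'
#' Emulates a comparative-CT experiment: a housekeeping gene with constant
#' expected Ct across samples, and target genes whose Ct is the housekeeper
#' Ct plus a gene-specific offset minus log2 of the sample's true relative
#' expression, with Gaussian well noise. Samples in the second group carry
#' the supplied fold changes; first-group samples sit at relative
#' expression 1, so any of them can serve as the reference sample downstream.
#'
#' @param fold_changes named numeric vector: true relative expression of each
#'   target gene in the treated group (all > 0).
#' @param n_per_group samples per group.
#' @param noise_sd Gaussian well-to-well noise in cycles (>= 0).
#' @param housekeeper housekeeping gene id.
#' @param groups two group labels (first = reference-level group).
#' @param base_ct expected housekeeper Ct.
#' @param target_offset cycles added to the housekeeper Ct for targets at
#'   relative expression 1.
#' @param n_wells replicate wells per (gene, sample).
#' @param seed integer seed.
#' @return Data frame of class `ct_plate` with columns gene, sample, group,
#'   well, ct.
#' @export
generate_ct_plate <- function(fold_changes, n_per_group = 3L, noise_sd = 0.2,
                              housekeeper = "YWHAG",
                              groups = c("IVV", "IVM"),
                              base_ct = 20, target_offset = 5,
                              n_wells = 3L, seed = 1L) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
    stop_validation("'fold_changes' must be a named vector of target genes")
  }
  if (any(fold_changes <= 0)) {
    stop_validation("'fold_changes' must be strictly positive")
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  n_per_group <- check_count(n_per_group, "n_per_group")
  n_wells <- check_count(n_wells, "n_wells")
  withr::with_seed(seed, {
    samples <- data.frame(
      sample = paste0(rep(groups, each = n_per_group), "_",
                      rep(seq_len(n_per_group), 2L)),
      group = rep(groups, each = n_per_group),
      stringsAsFactors = FALSE
    )
    genes <- c(housekeeper, names(fold_changes))
    grid <- expand.grid(well = seq_len(n_wells), sample = samples$sample,
                        gene = genes, stringsAsFactors = FALSE)
    grid$group <- samples$group[match(grid$sample, samples$sample)]
    rel <- ifelse(grid$group == groups[2],
                  fold_changes[grid$gene], 1)
    rel[grid$gene == housekeeper] <- 1
    offset <- ifelse(grid$gene == housekeeper, 0, target_offset)
    grid$ct <- base_ct + offset - log2(rel) +
      stats::rnorm(nrow(grid), 0, noise_sd)
    plate <- grid[, c("gene", "sample", "group", "well", "ct")]
    class(plate) <- c("ct_plate", "data.frame")
    plate
  })
}

#' Generate a noiseless-or-noisy primer dilution series
#'
#' Produces Ct values along a 10-fold dilution series from a known standard
#' curve (Ct = intercept + slope * log10(concentration)), for checking
#' [fit_standard_curve()].
#'
#' @param slope true slope of Ct on log10 concentration (negative).
#' @param intercept Ct at 1 ng/uL.
#' @param concentrations template concentrations in ng/uL.
#' @param noise_sd Gaussian Ct noise.
#' @param gene gene label.
#' @param seed integer seed.
#' @return Data frame with columns gene, concentration, ct.
#' @export
generate_dilution_series <- function(slope = -1 / log10(2), intercept = 22,
                                     concentrations = c(5, 0.5, 0.05),
                                     noise_sd = 0, gene = "target",
                                     seed = 1L) {
  check_number(noise_sd, "noise_sd", lower = 0)
  withr::with_seed(seed, {
    data.frame(
      gene = gene,
      concentration = concentrations,
      ct = intercept + slope * log10(concentrations) +
        stats::rnorm(length(concentrations), 0, noise_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate replicated oocyte maturation outcomes
#'
#' Draws, per replicate, the number of cultured oocytes reaching metaphase
#' II, cleaving, and forming blastocysts, under per-treatment stage
#' probabilities (each relative to the cultured total, non-increasing along
#' the developmental sequence). Stages are drawn sequentially conditional on
#' the previous stage so within-row monotonicity holds while marginal
#' expectations match the supplied probabilities. Nuclei counts per
#' blastocyst are Poisson around the treatment mean (floored at one nucleus).
#'
#' @param p_by_treatment named list; each element a length-3 numeric
#'   (P(MII), P(cleaved), P(blastocyst)) relative to cultured oocytes.
#' @param n_per_replicate oocytes cultured per replicate.
#' @param n_replicates replicates per treatment.
#' @param nuclei_means named numeric of per-treatment mean nuclei per
#'   blastocyst.
#' @param seed integer seed.
#' @return List with `outcomes` (treatment, replicate, n_cultured, n_mii,
#'   n_cleaved, n_blastocyst) and `nuclei` (treatment, replicate, count).
#' @export
generate_outcomes <- function(p_by_treatment = list(
                                CONTROL = c(0.73, 0.35, 0.28),
                                DKK1 = c(0.82, 0.38, 0.32)),
                              n_per_replicate = 150L,
                              n_replicates = 4L,
                              nuclei_means = c(CONTROL = 28.6, DKK1 = 32.7),
                              seed = 1L) {
  n_per_replicate <- check_count(n_per_replicate, "n_per_replicate")
  n_replicates <- check_count(n_replicates, "n_replicates")
  for (trt in names(p_by_treatment)) {
    p <- p_by_treatment[[trt]]
    if (length(p) != 3L) {
      stop_validation("stage probabilities for '", trt, "' must be length 3")
    }
    check_number(p, paste0("p_by_treatment$", trt), lower = 0, upper = 1,
                 allow_zero_len = TRUE)
    if (is.unsorted(rev(p))) {
      stop_validation("stage probabilities for '", trt,
                      "' must be non-increasing along MII -> cleavage -> ",
                      "blastocyst")
    }
  }
  withr::with_seed(seed, {
    rows <- list()
    nuc <- list()
    for (trt in names(p_by_treatment)) {
      p <- p_by_treatment[[trt]]
      for (r in seq_len(n_replicates)) {
        n_mii <- stats::rbinom(1, n_per_replicate, p[1])
        p_cl <- if (p[1] > 0) p[2] / p[1] else 0
        n_cl <- stats::rbinom(1, n_mii, p_cl)
        p_bl <- if (p[2] > 0) p[3] / p[2] else 0
        n_bl <- stats::rbinom(1, n_cl, p_bl)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = trt, replicate = r, n_cultured = n_per_replicate,
          n_mii = n_mii, n_cleaved = n_cl, n_blastocyst = n_bl,
          stringsAsFactors = FALSE
        )
        if (n_bl > 0 && trt %in% names(nuclei_means)) {
          nuc[[length(nuc) + 1L]] <- data.frame(
            treatment = trt, replicate = r,
            count = pmax(1L, stats::rpois(n_bl, nuclei_means[[trt]])),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    list(outcomes = do.call(rbind, rows),
         nuclei = if (length(nuc)) do.call(rbind, nuc) else
           data.frame(treatment = character(), replicate = integer(),
                      count = integer()))
  })
}
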
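## Agent-based simulator of the group-mating design: replicate vials of one
## focal male plus rival males housed with females over several daily
## observation windows.  Female receptivity is governed by a post-mating
## refractory clock (short clock = high-polyandry manipulation, long clock
## = control), and paternity of each female's daughters is drawn by a
## copulation-count raffle with optional last-male weighting.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_experiment()].  Defaults
#' mirror the group-mating design the package targets: groups of 1 focal +
#' 3 rival males with 4 females observed over 4 daily windows.
#'
#' @param n_groups Number of replicate groups (vials).
#' @param n_rivals Rival males per group (default 3).
#' @param n_females Females per group (default 4).
#' @param n_days Daily observation windows (default 4).
#' @param window_slots Potential copulation opportunities per window
#'   (default 12; one slot is the unit of the refractory clock).
#' @param focal_propensity Relative mating weight of the focal male against
#'   rivals of weight 1 (default 1.5, so the focal takes about one-third of
#'   matings against three rivals).
#' @param refractory_mean Mean female post-mating refractory duration in
#'   slots.  Small values emulate the high-polyandry (receptor-deleted)
#'   phenotype; large values emulate controls.  Durations are geometric.
#' @param fecundity_mean Mean daughters per mated female per day.
#' @param fecundity_treatment_multiplier Scalar on `fecundity_mean`
#'   (the high-polyandry arm of [make_paired_treatments()] uses a value
#'   below 1 to emulate its slightly reduced female productivity).
#' @param last_male_weight Multiplier (>= 1) on the raffle tickets of a
#'   female's final mate; 1 is a fair raffle.
#' @param n_replicates Number of experimental replicate blocks the groups
#'   are cycled over (default 2).
#' @param treatment Treatment label stamped on the output tables.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_groups = 29, n_rivals = 3, n_females = 4,
                       n_days = 4, window_slots = 12,
                       focal_propensity = 1.5, refractory_mean = 24,
                       fecundity_mean = 12,
                       fecundity_treatment_multiplier = 1,
                       last_male_weight = 1, n_replicates = 2,
                       treatment = "control") {
  cfg <- list(n_groups = as.integer(n_groups), n_rivals = as.integer(n_rivals),
              n_females = as.integer(n_females), n_days = as.integer(n_days),
              window_slots = as.integer(window_slots),
              focal_propensity = focal_propensity,
              refractory_mean = refractory_mean,
              fecundity_mean = fecundity_mean,
              fecundity_treatment_multiplier = fecundity_treatment_multiplier,
              last_male_weight = last_male_weight,
              n_replicates = as.integer(n_replicates),
              treatment = treatment)
  counts <- c("n_groups", "n_rivals", "n_females", "n_days", "window_slots",
              "n_replicates")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop_polysel("sim_config: ", nm, " must be a count >= 1")
    }
  }
  if (cfg$focal_propensity < 0) {
    stop_polysel("sim_config: focal_propensity must be >= 0")
  }
  if (cfg$refractory_mean < 0 || cfg$fecundity_mean < 0 ||
      cfg$fecundity_treatment_multiplier < 0) {
    stop_polysel("sim_config: rates must be >= 0")
  }
  if (cfg$last_male_weight < 1) {
    stop_polysel("sim_config: last_male_weight must be >= 1")
  }
  class(cfg) <- "sim_config"
  cfg
}

## Geometric refractory duration (in slots) with the requested mean; the
## memoryless distribution is the simplest one-parameter receptivity model.
draw_refractory <- function(n, mean_slots) {
  if (!is.finite(mean_slots)) return(rep(Inf, n))
  if (mean_slots <= 0) return(rep(0, n))
  rgeom(n, prob = 1 / (1 + mean_slots))
}

#' Simulate a group-mating experiment
#'
#' Runs the agent-based model for every group in `config`.  Within each
#' observation-window slot, one currently receptive female (uniformly
#' chosen, if any) mates with a male drawn with probability proportional
#' to his propensity, and her refractory clock is refreshed with a
#' geometric duration.  After the final day each female that mated draws
#' `Poisson(fecundity_mean * multiplier * n_days)` daughters, and sires are
#' assigned multinomially with tickets equal to per-male copulation counts,
#' the last mate's tickets multiplied by `last_male_weight`.  Females that
#' never mated produce no daughters.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; identical seed and config give identical
#'   output tables.
#' @return A list with `events`, `paternity` and `roster` data frames in
#'   the package's standard schemas, plus `truth`, a per-group record of
#'   the latent state: the male-by-female copulation-count matrix, the
#'   expected paternity weight of each male with each female, and realised
#'   per-female polyandry.
#' @export
simulate_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(config) {
  ev_list <- list(); pa_list <- list(); ro_list <- list(); truth <- list()
  for (g in seq_len(config$n_groups)) {
    gid <- sprintf("%s_g%03d", config$treatment, g)
    rep_id <- sprintf("rep%d", ((g - 1L) %% config$n_replicates) + 1L)
    males <- c("focal", paste0("rival", seq_len(config$n_rivals)))
    male_ids <- paste0(gid, "_", males)
    female_ids <- paste0(gid, "_female", seq_len(config$n_females))
    weights <- c(config$focal_propensity, rep(1, config$n_rivals))
    ro_list[[g]] <- data.frame(
      group_id = gid, treatment = config$treatment,
      id = c(male_ids, female_ids),
      sex = c(rep("male", length(male_ids)),
              rep("female", length(female_ids))),
      role = c("focal", rep("rival", config$n_rivals),
               rep("female", config$n_females)),
      stringsAsFactors = FALSE)

    cop <- matrix(0L, nrow = length(male_ids), ncol = length(female_ids),
                  dimnames = list(male_ids, female_ids))
    last_mate <- rep(NA_integer_, config$n_females)
    refractory <- rep(0, config$n_females)  # slots left until receptive
    ev_rows <- list()
    for (day in seq_len(config$n_days)) {
      order_in_day <- 0L
      for (slot in seq_len(config$window_slots)) {
        receptive <- which(refractory <= 0)
        refractory <- refractory - 1
        if (length(receptive) == 0) next
        f <- receptive[sample.int(length(receptive), 1L)]
        if (sum(weights) <= 0) next
        m <- sample.int(length(male_ids), 1L, prob = weights)
        cop[m, f] <- cop[m, f] + 1L
        last_mate[f] <- m
        refractory[f] <- draw_refractory(1, config$refractory_mean) + 1
        order_in_day <- order_in_day + 1L
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          group_id = gid, replicate_id = rep_id,
          treatment = config$treatment, day = day, order = order_in_day,
          male_id = male_ids[m], female_id = female_ids[f],
          stringsAsFactors = FALSE)
      }
    }
    if (length(ev_rows) > 0) {
      ev_list[[g]] <- do.call(rbind, ev_rows)
    }

    ## paternity raffle per female
    mu <- config$fecundity_mean * config$fecundity_treatment_multiplier *
      config$n_days
    weights_mat <- matrix(0, nrow = length(male_ids),
                          ncol = length(female_ids),
                          dimnames = dimnames(cop))
    pa_rows <- list()
    for (f in seq_len(config$n_females)) {
      tickets <- as.numeric(cop[, f])
      if (sum(tickets) == 0) next  # unmated female: no daughters
      tickets[last_mate[f]] <- tickets[last_mate[f]] * config$last_male_weight
      weights_mat[, f] <- tickets / sum(tickets)
      n_d <- rpois(1, mu)
      sired <- if (n_d > 0) {
        as.integer(rmultinom(1, n_d, prob = tickets))
      } else integer(length(male_ids))
      pa_rows[[length(pa_rows) + 1L]] <- data.frame(
        group_id = gid, female_id = female_ids[f],
        daughters_focal = sired[1],
        daughters_other = sum(sired[-1]),
        stringsAsFactors = FALSE)
    }
    if (length(pa_rows) > 0) pa_list[[g]] <- do.call(rbind, pa_rows)

    truth[[gid]] <- list(
      copulation_counts = cop,
      paternity_weights = weights_mat,
      polyandry = setNames(colSums(cop > 0), female_ids))
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(group_id = character(), replicate_id = character(),
               treatment = character(), day = integer(), order = integer(),
               male_id = character(), female_id = character(),
               stringsAsFactors = FALSE)
  paternity <- if (length(pa_list)) do.call(rbind, pa_list) else
    data.frame(group_id = character(), female_id = character(),
               daughters_focal = integer(), daughters_other = integer(),
               stringsAsFactors = FALSE)
  roster <- do.call(rbind, ro_list)
  rownames(events) <- rownames(paternity) <- rownames(roster) <- NULL
  list(events = events, paternity = paternity, roster = roster,
       truth = c(truth, list(config = config)))
}

#' Simulate a paired treatment contrast
#'
#' Produces a control-like dataset (long refractory period, full fecundity)
#' and a high-polyandry dataset (short refractory period, slightly reduced
#' fecundity), sharing all other parameters of `base`, emulating the
#' receptor-deletion manipulation of female remating.
#'
#' @param base A [sim_config()] used as the template for both arms.
#' @param seed Integer seed; the two arms use derived, distinct streams.
#' @param refractory_control,refractory_high Mean refractory durations
#'   (slots) for the two arms.
#' @param fecundity_multiplier_high Fecundity multiplier for the
#'   high-polyandry arm (< 1; emulates its reduced female productivity).
#' @return A named list with elements `control` and `high_polyandry`, each
#'   a [simulate_experiment()] result.
#' @export
make_paired_treatments <- function(base = sim_config(), seed = NULL,
                                   refractory_control = 24,
                                   refractory_high = 4,
                                   fecundity_multiplier_high = 0.85) {
  cfg_c <- base
  cfg_c$refractory_mean <- refractory_control
  cfg_c$fecundity_treatment_multiplier <- 1
  cfg_c$treatment <- "control"
  cfg_h <- base
  cfg_h$refractory_mean <- refractory_high
  cfg_h$fecundity_treatment_multiplier <- fecundity_multiplier_high
  cfg_h$treatment <- "high_polyandry"
  s1 <- if (is.null(seed)) NULL else substream_seed(seed, "simulate")
  s2 <- if (is.null(seed)) NULL else substream_seed(seed + 1L, "simulate")
  list(control = simulate_experiment(cfg_c, seed = s1),
       high_polyandry = simulate_experiment(cfg_h, seed = s2))
}
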
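## Core data handling: readers/writers for the three experiment tables
## (mating events, paternity counts, group rosters), validation against the
## group design, and per-focal-male summarisation into the fitness
## components T, M, P and N used by every downstream analysis.
##
## Table schemas (CSV or TSV, header required, UTF-8):
##   events:    group_id, replicate_id, treatment, day, order, male_id, female_id
##   paternity: group_id, female_id, daughters_focal, daughters_other
##   roster:    group_id, treatment, id, sex, role
## Delimiter is chosen from the file extension (.tsv/.tab/.txt -> tab,
## otherwise comma).

events_cols <- c("group_id", "replicate_id", "treatment", "day", "order",
                 "male_id", "female_id")
paternity_cols <- c("group_id", "female_id", "daughters_focal",
                    "daughters_other")
roster_cols <- c("group_id", "treatment", "id", "sex", "role")

delim_for <- function(path) {
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop_polysel("file not found: ", path)
  x <- read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE,
                check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop_polysel("missing column(s) in ", basename(path), ": ",
                 paste(missing, collapse = ", "))
  }
  x[required]
}

write_table_checked <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mating-event table
#'
#' One row per observed copulation: which male mated which female, in which
#' group, on which day, and in what order within that group-day.  If a
#' `roster` is supplied the male and female identifiers are checked against
#' the group's membership.
#'
#' @param path Path to a CSV/TSV file with columns `group_id`,
#'   `replicate_id`, `treatment`, `day`, `order`, `male_id`, `female_id`.
#' @param roster Optional roster data frame (see [read_roster()]) used to
#'   validate identifiers.
#' @return A data frame of validated events sorted by group, day and order.
#' @export
read_mating_events <- function(path, roster = NULL) {
  ev <- read_table_checked(path, events_cols)
  ev$day <- as.integer(ev$day)
  ev$order <- as.integer(ev$order)
  validate_events(ev, roster)
}

#' @rdname read_mating_events
#' @param events A mating-event data frame to write.
#' @export
write_mating_events <- function(events, path) {
  write_table_checked(events[events_cols], path)
}

#' Read a paternity table
#'
#' One row per (group, female): how many of her daughters were sired by the
#' group's focal male and how many by other males.  Only daughters are
#' scored because only they carry the informative eye markers.
#'
#' @param path Path to a CSV/TSV file with columns `group_id`, `female_id`,
#'   `daughters_focal`, `daughters_other`.
#' @return A data frame of paternity records.
#' @export
read_paternity <- function(path) {
  pa <- read_table_checked(path, paternity_cols)
  pa$daughters_focal <- as.integer(pa$daughters_focal)
  pa$daughters_other <- as.integer(pa$daughters_other)
  if (any(pa$daughters_focal < 0 | pa$daughters_other < 0)) {
    stop_polysel("negative daughter counts in paternity table")
  }
  key <- paste(pa$group_id, pa$female_id)
  if (anyDuplicated(key)) {
    stop_polysel("duplicate (group_id, female_id) in paternity table: ",
                 key[which(duplicated(key))[1]])
  }
  pa
}

#' @rdname read_paternity
#' @param paternity A paternity data frame to write.
#' @export
write_paternity <- function(paternity, path) {
  write_table_checked(paternity[paternity_cols], path)
}

#' Read a group roster
#'
#' Lists the members of every group: one focal male, his rival males, and
#' the females, together with the group's treatment label.
#'
#' @param path Path to a CSV/TSV file with columns `group_id`, `treatment`,
#'   `id`, `sex` (`"male"`/`"female"`) and `role` (`"focal"`, `"rival"` or
#'   `"female"`).
#' @return A validated roster data frame.
#' @export
read_roster <- function(path) {
  ro <- read_table_checked(path, roster_cols)
  validate_roster(ro)
}

#' @rdname read_roster
#' @param roster A roster data frame to write.
#' @export
write_roster <- function(roster, path) {
  write_table_checked(roster[roster_cols], path)
}

validate_roster <- function(roster) {
  for (g in unique(roster$group_id)) {
    sub <- roster[roster$group_id == g, ]
    if (anyDuplicated(sub$id)) {
      stop_polysel("duplicate ids within group ", g)
    }
    if (sum(sub$role == "focal") != 1) {
      stop_polysel("group ", g, " must have exactly one focal male, found ",
                   sum(sub$role == "focal"))
    }
    bad_sex <- (sub$role %in% c("focal", "rival") & sub$sex != "male") |
      (sub$role == "female" & sub$sex != "female")
    if (any(bad_sex)) {
      stop_polysel("inconsistent sex/role for id ", sub$id[bad_sex][1],
                   " in group ", g)
    }
  }
  roster
}

validate_events <- function(events, roster = NULL) {
  if (any(events$day < 1)) {
    bad <- which(events$day < 1)[1]
    stop_polysel("day must be >= 1 (row ", bad, ")")
  }
  key <- paste(events$group_id, events$day, events$order)
  if (anyDuplicated(key)) {
    stop_polysel("duplicate copulation order within group-day: ",
                 key[which(duplicated(key))[1]])
  }
  if (!is.null(roster)) {
    for (g in unique(events$group_id)) {
      sub <- events[events$group_id == g, ]
      members <- roster$id[roster$group_id == g]
      unknown <- setdiff(c(sub$male_id, sub$female_id), members)
      if (length(unknown) > 0) {
        stop_polysel("id(s) not in the roster of group ", g, ": ",
                     paste(unknown, collapse = ", "))
      }
    }
  }
  events[order(events$group_id, events$day, events$order), , drop = FALSE]
}

#' Summarise focal-male fitness components
#'
#' Collapses the raw event and paternity tables into one row per focal
#' male with the components of his reproductive success:
#' \describe{
#'   \item{`mating_frequency`}{total number of copulations;}
#'   \item{`M`}{mating success, the number of unique female mates;}
#'   \item{`repetitive_rate`}{mean copulations per unique mate
#'     (`mating_frequency / M`; 1 means no re-mating);}
#'   \item{`N`}{mate productivity, the arithmetic mean number of daughters
#'     produced by his mates;}
#'   \item{`P`}{paternity share, pooled over his mates: daughters he sired
#'     divided by all daughters his mates produced;}
#'   \item{`T`}{reproductive success, total daughters sired.}
#' }
#' With `P` defined as the pooled share and `N` as the arithmetic mean,
#' the identity `T = M * N * P` holds exactly for every male with at least
#' one mate, which is what makes the multiplicative variance decomposition
#' in [decompose_variance()] exact.  `mean_share_per_mate` (the per-female
#' proportion of daughters sired, averaged over mates) is also reported for
#' descriptive use.  Males that never mated get `T = 0` and `NA` for `P`,
#' `N` and `repetitive_rate`.  `vial_fecundity` is the total number of
#' daughters produced in the male's group (a standard covariate for the
#' gradient models).
#'
#' @param events Mating-event data frame (see [read_mating_events()]).
#' @param paternity Paternity data frame (see [read_paternity()]).
#' @param roster Roster data frame (see [read_roster()]).
#' @return A data frame with one row per focal male.
#' @export
compute_male_summaries <- function(events, paternity, roster) {
  roster <- validate_roster(roster)
  events <- validate_events(events, roster)
  groups <- unique(roster$group_id)
  rows <- lapply(groups, function(g) {
    ros <- roster[roster$group_id == g, ]
    ev <- events[events$group_id == g, ]
    pa <- paternity[paternity$group_id == g, ]
    focal <- ros$id[ros$role == "focal"]
    fev <- ev[ev$male_id == focal, ]
    mates <- unique(fev$female_id)
    # a focal-sired daughter from a female he never mated is a data error
    incons <- pa$female_id[pa$daughters_focal > 0 &
                             !(pa$female_id %in% mates)]
    if (length(incons) > 0) {
      stop_polysel("group ", g, ": focal-sired daughters recorded for ",
                   "female(s) never mated by the focal male: ",
                   paste(incons, collapse = ", "))
    }
    vial_fec <- sum(pa$daughters_focal + pa$daughters_other)
    treatment <- ros$treatment[1]
    replicate_id <- if (nrow(ev) > 0) ev$replicate_id[1] else NA_character_
    if (length(mates) == 0) {
      return(data.frame(
        male_id = focal, group_id = g, replicate_id = replicate_id,
        treatment = treatment, mating_frequency = 0L, M = 0L,
        repetitive_rate = NA_real_, N = NA_real_, P = NA_real_, T = 0,
        mean_share_per_mate = NA_real_, vial_fecundity = vial_fec,
        stringsAsFactors = FALSE))
    }
    missing_pa <- setdiff(mates, pa$female_id)
    if (length(missing_pa) > 0) {
      stop_polysel("group ", g, ": no paternity record for mated female(s) ",
                   paste(missing_pa, collapse = ", "))
    }
    pm <- pa[match(mates, pa$female_id), ]
    totals <- pm$daughters_focal + pm$daughters_other
    shares <- ifelse(totals > 0, pm$daughters_focal / totals, NA_real_)
    data.frame(
      male_id = focal, group_id = g, replicate_id = replicate_id,
      treatment = treatment,
      mating_frequency = nrow(fev),
      M = length(mates),
      repetitive_rate = nrow(fev) / length(mates),
      N = mean(totals),
      P = if (sum(totals) > 0) sum(pm$daughters_focal) / sum(totals)
          else NA_real_,
      T = sum(pm$daughters_focal),
      mean_share_per_mate = mean(shares, na.rm = TRUE),
      vial_fecundity = vial_fec,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-female polyandry counts
#'
#' @param events Mating-event data frame.
#' @return Data frame with `group_id`, `female_id`, `n_mates` (unique male
#'   partners) and `n_copulations`.
#' @export
female_polyandry <- function(events) {
  key <- interaction(events$group_id, events$female_id, drop = TRUE)
  splits <- split(events, key)
  out <- do.call(rbind, lapply(splits, function(s) {
    data.frame(group_id = s$group_id[1], female_id = s$female_id[1],
               n_mates = length(unique(s$male_id)),
               n_copulations = nrow(s), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group_id, out$female_id), , drop = FALSE]
}
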
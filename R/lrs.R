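#' Attribute fish to spawning cohorts
#'
#' Returning adults enter fresh water from late spring but spawn in the
#' winter of the same calendar year, so by default a fish returning in year
#' `t` belongs to spawning cohort `t`.  Fish with non-standard life
#' histories (repeat spawners, delayed spawning) are handled through an
#' explicit override table that attributes a fish to one or more cohorts,
#' optionally with weights.
#'
#' @param fish data.frame of fish records with at least `fish_id` and
#'   `return_year`.
#' @param overrides optional data.frame with columns `fish_id`, `cohort`
#'   and, optionally, `weight`; a fish listed here gets exactly the listed
#'   cohorts instead of the default.
#'
#' @return `fish` with a list-column `spawning_cohorts` added.  Fish with no
#'   resolvable cohort (missing `return_year` and no override) are dropped;
#'   the number dropped is recorded in attribute `n_excluded` and reported
#'   via a message.
#' @examples
#' fish <- data.frame(fish_id = c("a", "b"), return_year = c(1977, 1978))
#' ov <- data.frame(fish_id = "b", cohort = c(1978, 1980))
#' assign_spawning_cohorts(fish, ov)$spawning_cohorts
#' @export
assign_spawning_cohorts <- function(fish, overrides = NULL) {
  if (!"return_year" %in% names(fish)) {
    stop("`fish` must have a `return_year` column")
  }
  if (!is.null(overrides)) {
    need <- c("fish_id", "cohort")
    if (!all(need %in% names(overrides))) {
      stop("`overrides` must have columns `fish_id` and `cohort`")
    }
    if (is.null(overrides$weight)) overrides$weight <- 1
  }
  overridden <- if (is.null(overrides)) rep(FALSE, nrow(fish)) else
    fish$fish_id %in% overrides$fish_id
  cohorts <- vector("list", nrow(fish))
  # default rule, vectorised: return year t -> spawning cohort t
  default_ok <- !overridden & !is.na(fish$return_year)
  cohorts[default_ok] <- lapply(fish$return_year[default_ok], function(y) {
    list(cohort = y, weight = 1)
  })
  for (i in which(overridden)) {
    o <- overrides[overrides$fish_id == fish$fish_id[i], , drop = FALSE]
    cohorts[[i]] <- list(cohort = o$cohort,
                         weight = o$weight / sum(o$weight))
  }
  resolved <- !vapply(cohorts, is.null, logical(1L))
  n_excluded <- sum(!resolved)
  if (n_excluded > 0L) {
    message(n_excluded, " fish had no resolvable spawning cohort and were excluded")
  }
  out <- fish[resolved, , drop = FALSE]
  out$spawning_cohorts <- cohorts[resolved]
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Expand cohort attributions to long form
#'
#' @param fish output of [assign_spawning_cohorts()].
#' @return data.frame with one row per (fish, cohort): `fish_id`, `cohort`,
#'   `weight` (weights of one fish sum to 1).
#' @export
cohort_assignments <- function(fish) {
  if (is.null(fish$spawning_cohorts)) {
    stop("run `assign_spawning_cohorts()` first")
  }
  n_each <- vapply(fish$spawning_cohorts,
                   function(e) length(e$cohort), integer(1L))
  data.frame(
    fish_id = rep(fish$fish_id, n_each),
    cohort = unlist(lapply(fish$spawning_cohorts, `[[`, "cohort")),
    weight = unlist(lapply(fish$spawning_cohorts, `[[`, "weight")),
    stringsAsFactors = FALSE
  )
}

#' Lifetime reproductive success from a parentage table
#'
#' LRS of a fish is the number of distinct adult offspring genetically
#' assigned to it.  Every fish in the table gets a value; a fish with no
#' links has an explicit LRS of 0.  A two-parent offspring contributes one
#' offspring to each parent's LRS.
#'
#' @param parentage data.frame of links with columns `offspring_id`,
#'   `parent_id`.
#' @param fish data.frame of fish records with `fish_id`.
#' @return data.frame (`lrs_table`): `fish_id`, `lrs`.  The column sum of
#'   `lrs` equals the number of distinct (offspring, parent) links.
#' @examples
#' fish <- data.frame(fish_id = c("p1", "p2", "p3"))
#' ped <- data.frame(offspring_id = c("o1", "o2", "o3"),
#'                   parent_id = c("p1", "p1", "p2"))
#' compute_lrs(ped, fish)
#' @export
compute_lrs <- function(parentage, fish) {
  need <- c("offspring_id", "parent_id")
  if (!all(need %in% names(parentage))) {
    stop("`parentage` must have columns `offspring_id` and `parent_id`")
  }
  if (anyDuplicated(fish$fish_id)) stop("duplicate `fish_id` in fish table")
  links <- unique(parentage[, need, drop = FALSE])
  orphans <- setdiff(links$parent_id, fish$fish_id)
  if (length(orphans) > 0L) {
    stop("parent ids absent from fish table: ",
         paste(utils::head(orphans, 5L), collapse = ", "),
         if (length(orphans) > 5L) sprintf(" (and %d more)",
                                           length(orphans) - 5L) else "")
  }
  counts <- table(factor(links$parent_id, levels = fish$fish_id))
  out <- data.frame(fish_id = fish$fish_id,
                    lrs = as.integer(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("lrs_table", "data.frame")
  out
}

#' Mating-pair classes and grand-offspring means
#'
#' For offspring with both parents assigned, classifies each mating by
#' parental provenance (captive x captive, captive x wild, wild x wild) and
#' reports the count, proportion and mean LRS (number of grand-offspring)
#' per class, together with the same summary keyed by the offspring's number
#' of captive-bred parents (0, 1, 2).
#'
#' @param parentage data.frame of links with `offspring_id`, `parent_id`,
#'   `n_parents_assigned`.
#' @param fish fish table with `fish_id` and `provenance`.
#' @param lrs an `lrs_table` from [compute_lrs()]; offspring absent from it
#'   are treated as LRS 0.
#' @return list with data.frames `pair_type` (class in `"CC"`, `"CW"`,
#'   `"WW"`) and `by_captive_parents` (0/1/2 captive parents); each has
#'   `n_offspring`, `proportion`, `mean_lrs`.  Proportions sum to 1.
#'   With no two-parent offspring both tables are empty and a warning is
#'   raised.
#' @export
pair_type_summary <- function(parentage, fish, lrs) {
  if (!"n_parents_assigned" %in% names(parentage)) {
    stop("`parentage` must have an `n_parents_assigned` column")
  }
  two <- parentage[parentage$n_parents_assigned == 2L, , drop = FALSE]
  empty <- data.frame(n_offspring = integer(0), proportion = numeric(0),
                      mean_lrs = numeric(0))
  if (nrow(two) == 0L) {
    warning("no offspring with two assigned parents")
    return(list(pair_type = cbind(pair = character(0), empty),
                by_captive_parents = cbind(n_captive_parents = integer(0),
                                           empty)))
  }
  prov <- fish$provenance[match(two$parent_id, fish$fish_id)]
  if (anyNA(prov)) stop("two-parent links reference parents missing a provenance")
  n_cap <- tapply(prov == "captive", two$offspring_id, sum)
  # an offspring with only one of its two links in the table cannot be typed
  n_links <- tapply(rep(1L, nrow(two)), two$offspring_id, sum)
  ok <- n_links == 2L
  if (!all(ok)) {
    warning(sum(!ok), " two-parent offspring had only one link present; dropped")
    n_cap <- n_cap[ok]
  }
  off_ids <- names(n_cap)
  off_lrs <- lrs$lrs[match(off_ids, lrs$fish_id)]
  off_lrs[is.na(off_lrs)] <- 0
  summarize <- function(key, levels) {
    f <- factor(key, levels = levels)
    n <- as.integer(table(f))
    ml <- as.numeric(tapply(off_lrs, f, mean))
    ml[is.na(ml) & n == 0L] <- NaN
    data.frame(n_offspring = n, proportion = n / sum(n), mean_lrs = ml)
  }
  pair <- c("WW", "CW", "CC")[as.integer(n_cap) + 1L]
  pt <- cbind(pair = factor(c("CC", "CW", "WW"), c("CC", "CW", "WW")),
              summarize(pair, c("CC", "CW", "WW")))
  bc <- cbind(n_captive_parents = 0:2,
              summarize(as.integer(n_cap), 0:2))
  list(pair_type = pt, by_captive_parents = bc)
}
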
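#' Walk Score walkability categories
#'
#' Default mapping of a 0-100 neighbourhood walkability score to the four
#' published Walk Score categories. The discordance rule contrasts the two
#' car-oriented categories against the two walkable ones.
#'
#' @return A tibble with columns `category`, `lower` and `upper`
#'   (inclusive score bounds), and `side` (`"low"` for car dependent /
#'   somewhat walkable, `"high"` for very walkable / walker's paradise).
#' @export
walk_score_bins <- function() {
  tibble(
    category = c("car dependent", "somewhat walkable",
                 "very walkable", "walker's paradise"),
    lower = c(0, 50, 70, 90),
    upper = c(50, 70, 90, 100),
    side = c("low", "low", "high", "high")
  )
}

walk_category <- function(score, bins = walk_score_bins()) {
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    abort("walkability scores must lie in [0, 100]")
  }
  idx <- vapply(score, function(s) {
    if (is.na(s)) return(NA_integer_)
    # upper bounds are exclusive except the topmost category
    which(s >= bins$lower & (s < bins$upper | bins$upper >= 100))[1]
  }, integer(1))
  bins$category[idx]
}

#' Classify physical-activity discordance within a twin pair
#'
#' A pair is discordant for physical activity when one twin accumulates at
#' least 150 minutes of moderate-to-vigorous physical activity (MVPA) per
#' week and the co-twin less than 150 minutes. Vectorised over pairs.
#'
#' @param mvpa_a,mvpa_b MVPA minutes/week of the two pair members.
#' @param threshold Minutes/week cut point (default 150).
#' @return A tibble with columns `discordant` (logical), `low` and `high`
#'   (1 or 2, index of the low/high member; NA when concordant).
#' @examples
#' pa_discordance(66, 266)
#' pa_discordance(c(150, 150), c(149, 150))
#' @export
pa_discordance <- function(mvpa_a, mvpa_b, threshold = 150) {
  if (any(c(mvpa_a, mvpa_b) < 0, na.rm = TRUE)) {
    abort("MVPA minutes must be non-negative")
  }
  hi_a <- mvpa_a >= threshold
  hi_b <- mvpa_b >= threshold
  disc <- xor(hi_a, hi_b)
  tibble(
    discordant = disc,
    low = ifelse(disc, ifelse(hi_a, 2L, 1L), NA_integer_),
    high = ifelse(disc, ifelse(hi_a, 1L, 2L), NA_integer_)
  )
}

#' Classify neighbourhood-walkability discordance within a twin pair
#'
#' Discordant when one twin lives in a car dependent or somewhat walkable
#' neighbourhood and the co-twin in a very walkable or walker's paradise
#' neighbourhood, under a configurable score-to-category map.
#'
#' @param score_a,score_b Walkability scores (0-100) of the two members.
#' @param bins Category map as produced by [walk_score_bins()].
#' @return A tibble with columns `discordant`, `low`, `high`,
#'   `category_a`, `category_b`.
#' @examples
#' walkability_discordance(25.7, 82.0)
#' @export
walkability_discordance <- function(score_a, score_b, bins = walk_score_bins()) {
  cat_a <- walk_category(score_a, bins)
  cat_b <- walk_category(score_b, bins)
  side <- setNames(bins$side, bins$category)
  low_a <- side[cat_a] == "low"
  low_b <- side[cat_b] == "low"
  disc <- xor(low_a, low_b)
  tibble(
    discordant = unname(disc),
    low = ifelse(disc, ifelse(low_a, 1L, 2L), NA_integer_),
    high = ifelse(disc, ifelse(low_a, 2L, 1L), NA_integer_),
    category_a = cat_a,
    category_b = cat_b
  )
}

#' Classify body-mass-index discordance within a twin pair
#'
#' Discordant when the within-pair BMI difference is at least
#' `min_diff` kg/m^2 (default 5).
#'
#' @param bmi_a,bmi_b BMI (kg/m^2) of the two members.
#' @param min_diff Minimum absolute within-pair difference.
#' @return A tibble with columns `discordant`, `low`, `high`.
#' @examples
#' bmi_discordance(28.4, 35.2)
#' bmi_discordance(30, 34.9)
#' @export
bmi_discordance <- function(bmi_a, bmi_b, min_diff = 5) {
  if (any(c(bmi_a, bmi_b) <= 0, na.rm = TRUE)) abort("BMI must be positive")
  disc <- abs(bmi_a - bmi_b) >= min_diff
  tibble(
    discordant = disc,
    low = ifelse(disc, ifelse(bmi_a <= bmi_b, 1L, 2L), NA_integer_),
    high = ifelse(disc, ifelse(bmi_a <= bmi_b, 2L, 1L), NA_integer_)
  )
}

# Reshape a participant-level trait table into one row per pair with
# member 1/2 columns. Pairs without exactly two same-sex members are
# dropped with a message.
pairs_wide <- function(traits) {
  counts <- traits |> count(.data$pair_id)
  bad <- counts$pair_id[counts$n != 2L]
  if (length(bad)) {
    inform(paste0("dropping incomplete pair(s): ", paste(bad, collapse = ", ")))
    traits <- traits |> filter(!.data$pair_id %in% bad)
  }
  traits |>
    arrange(.data$pair_id, .data$id) |>
    group_by(.data$pair_id) |>
    mutate(member = row_number()) |>
    ungroup() |>
    pivot_wider(id_cols = c("pair_id", "sex"),
                names_from = "member",
                values_from = c("id", "mvpa_min_week", "walkability_score",
                                "bmi"),
                names_sep = "_")
}

#' Classify all trait discordances for a twin cohort
#'
#' Applies the physical-activity, walkability and BMI discordance rules to
#' every complete pair in a participant trait table. Member order within a
#' pair does not affect any flag.
#'
#' @param traits Participant table with columns `id`, `pair_id`, `sex`,
#'   `mvpa_min_week`, `walkability_score`, `bmi` (one row per participant).
#' @param bins Walkability category map, see [walk_score_bins()].
#' @return One row per pair: `pair_id`, `sex`, and for each trait in
#'   `pa`, `walkability`, `bmi` a `<trait>_discordant` flag plus
#'   `<trait>_low_id` / `<trait>_high_id` member ids (NA for concordant
#'   pairs).
#' @export
classify_discordance <- function(traits, bins = walk_score_bins()) {
  wide <- pairs_wide(traits)
  pa <- pa_discordance(wide$mvpa_min_week_1, wide$mvpa_min_week_2)
  wk <- walkability_discordance(wide$walkability_score_1,
                                wide$walkability_score_2, bins)
  bm <- bmi_discordance(wide$bmi_1, wide$bmi_2)
  pick <- function(idx, wide) {
    ifelse(is.na(idx), NA_character_,
           ifelse(idx == 1L, wide$id_1, wide$id_2))
  }
  tibble(
    pair_id = wide$pair_id,
    sex = wide$sex,
    pa_discordant = pa$discordant,
    pa_low_id = pick(pa$low, wide),
    pa_high_id = pick(pa$high, wide),
    walkability_discordant = wk$discordant,
    walkability_low_id = pick(wk$low, wide),
    walkability_high_id = pick(wk$high, wide),
    bmi_discordant = bm$discordant,
    bmi_low_id = pick(bm$low, wide),
    bmi_high_id = pick(bm$high, wide)
  )
}

#' Remove low-mapping samples together with their co-twins
#'
#' Samples with an overall read mapping rate below `min_rate` are removed
#' from the analysis along with the corresponding co-twin, so the retained
#' set always consists of intact pairs.
#'
#' @param traits Participant table with `id`, `pair_id` and `mapping_rate`
#'   columns (rate as a fraction in `[0, 1]`).
#' @param min_rate Minimum acceptable mapping rate (default 0.70).
#' @return The filtered participant tibble; the removed pair ids are
#'   attached as attribute `"removed_pairs"`.
#' @export
apply_mapping_qc <- function(traits, min_rate = 0.70) {
  if (!"mapping_rate" %in% names(traits) || anyNA(traits$mapping_rate)) {
    abort("`traits` must carry a complete `mapping_rate` column")
  }
  bad_pairs <- unique(traits$pair_id[traits$mapping_rate < min_rate])
  kept <- traits |> filter(!.data$pair_id %in% bad_pairs)
  # intact-pair guarantee also protects against pre-existing singletons
  sizes <- kept |> count(.data$pair_id)
  kept <- kept |> filter(.data$pair_id %in% sizes$pair_id[sizes$n == 2L])
  if (nrow(kept) == 0L) {
    warn("mapping QC removed every pair")
  }
  attr(kept, "removed_pairs") <- bad_pairs
  kept
}

#' Arms of a discordance comparison
#'
#' Builds the two unpaired comparison groups (low vs high arm) for one
#' trait comparison in one sex, using only discordant pairs.
#'
#' @param traits Participant table (post-QC).
#' @param comparison One of `"pa"`, `"walkability"`, `"bmi"`.
#' @param sex `"M"` or `"F"`; the pipeline always hard-partitions by sex.
#' @param bins Walkability category map.
#' @return A tibble with columns `id`, `pair_id`, `arm` (`"low"`/`"high"`),
#'   ordered low arm first.
#' @export
comparison_groups <- function(traits, comparison = c("pa", "walkability", "bmi"),
                              sex = c("M", "F"), bins = walk_score_bins()) {
  comparison <- match.arg(comparison)
  sex <- match.arg(sex)
  traits <- traits |> filter(.data$sex == !!sex)
  if (nrow(traits) == 0L) abort(paste0("no samples of sex ", sex))
  flags <- classify_discordance(traits, bins)
  disc <- flags |> filter(.data[[paste0(comparison, "_discordant")]])
  if (nrow(disc) == 0L) {
    abort(paste0("no ", sex, " pairs discordant for ", comparison))
  }
  bind_rows(
    tibble(id = disc[[paste0(comparison, "_low_id")]],
           pair_id = disc$pair_id, arm = "low"),
    tibble(id = disc[[paste0(comparison, "_high_id")]],
           pair_id = disc$pair_id, arm = "high")
  )
}
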
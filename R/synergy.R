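#' Predicted outcomes for all 16 regimens
#'
#' Simulates every regimen under one parameter set and reports both
#' tumor-size outcomes together with percent inhibition relative to the
#' untreated control `SX`.
#'
#' @param params A parameter tibble.
#' @param ... Passed to [simulate_model()].
#' @return A tibble with one row per regimen (canonical order): `regimen`,
#'   `n_components`, `type_I`, `type_II`, `inhibition_I`, `inhibition_II`
#'   (percent).
#' @examples
#' predict_all_regimens(default_truth())
#' @export
predict_all_regimens <- function(params, ...) {
  regs <- enumerate_regimens()
  oc <- purrr::map(regs$label, function(lb) {
    outcomes(simulate_model(params, lb, ...))
  }) |> list_rbind()
  out <- bind_cols(regs[, c("label", "n_components")], oc)
  out <- rename(out, regimen = "label")
  ctrl <- out[out$regimen == "SX", ]
  out$inhibition_I <- percent_inhibition(out$type_I, ctrl$type_I)
  out$inhibition_II <- percent_inhibition(out$type_II, ctrl$type_II)
  out
}

#' Rank regimens by efficacy
#'
#' Orders regimens by descending percent inhibition for one outcome type.
#' Exact ties are broken lexicographically by label and flagged.
#'
#' @param outcomes Output of [predict_all_regimens()].
#' @param type `"I"` (instantaneous) or `"II"` (average outcome).
#' @return The outcome tibble ordered by rank, with columns `rank`,
#'   `inhibition` and `tied` added.
#' @export
rank_regimens <- function(outcomes, type = c("I", "II")) {
  type <- match.arg(type)
  col <- paste0("inhibition_", type)
  tbl <- outcomes |>
    mutate(inhibition = .data[[col]]) |>
    arrange(desc(.data$inhibition), .data$regimen)
  tbl$rank <- seq_len(nrow(tbl))
  tbl$tied <- duplicated(tbl$inhibition) | duplicated(tbl$inhibition, fromLast = TRUE)
  tbl
}

#' Ranks of component-containing regimens by combination size
#'
#' For a treatment component (e.g. `AR`), extracts the within-size ranks
#' of the regimens containing it: among the 4 single treatments, the 6
#' two-way combinations and the 4 three-way combinations.
#'
#' @param outcomes Output of [predict_all_regimens()].
#' @param component One of `"CX"`, `"V"`, `"AI"`, `"AR"`.
#' @param type Outcome type, `"I"` or `"II"`.
#' @return A tibble `n_components`, `regimen`, `rank_within_size`.
#' @export
component_ranks <- function(outcomes, component, type = c("I", "II")) {
  type <- match.arg(type)
  component <- match.arg(component, regimen_components)
  flag <- tolower(component)
  regs <- enumerate_regimens()
  col <- paste0("inhibition_", type)
  tbl <- left_join(outcomes, regs[, c("label", tolower(regimen_components))],
                   by = c("regimen" = "label"), suffix = c("", ".y"))
  tbl |>
    filter(.data$n_components %in% 1:3) |>
    group_by(.data$n_components) |>
    arrange(desc(.data[[col]]), .data$regimen, .by_group = TRUE) |>
    mutate(rank_within_size = dplyr::row_number()) |>
    ungroup() |>
    filter(.data[[flag]]) |>
    select("n_components", "regimen", "rank_within_size")
}

#' Bliss combination index
#'
#' Compares the observed combined effect of two disjoint treatment
#' groups with the Bliss-independence expectation built from their
#' individual effects: `CI = (e_a + e_b - e_a * e_b) / e_ab`. Effects are
#' tumor-inhibition fractions in `[0, 1)`. `CI < 1` is synergistic,
#' `CI = 1` additive, `CI > 1` antagonistic. Effects are clipped to
#' `[0, 0.999]` (negative inhibition is treated as 0, with a warning);
#' a non-positive combined effect leaves the index undefined (`NA`).
#'
#' @param e_a,e_b Individual inhibition fractions.
#' @param e_ab Combined inhibition fraction.
#' @return The combination index (vectorized).
#' @examples
#' bliss_ci(0.3, 0.4, 0.58)  # = 1: exact Bliss additivity
#' bliss_ci(0.5, 0.5, 0.9)   # < 1: synergy
#' @export
bliss_ci <- function(e_a, e_b, e_ab) {
  clip <- function(e) {
    if (any(e < 0, na.rm = TRUE)) {
      warn("Negative inhibition fraction(s) treated as 0 in Bliss CI.")
    }
    pmin(pmax(e, 0), 0.999)
  }
  e_a <- clip(e_a); e_b <- clip(e_b)
  expected <- e_a + e_b - e_a * e_b
  ifelse(is.na(e_ab) | e_ab <= 0, NA_real_, expected / e_ab)
}

#' Treatment groups for pairwise combination analysis
#'
#' A treatment group is a non-empty subset of the four components treated
#' as one unit in a pairwise combination; e.g. the pair
#' `((CX + V), AR)` asks whether adding Treg depletion to the combined
#' castration-plus-vaccination treatment is synergistic. Two groups are
#' combinable only when disjoint. The Bliss index used here is pairwise
#' only: `(A + B) + C` is analyzable, the three-way split `A + B + C` is
#' not.
#'
#' @return A tibble: `group` (display label, parenthesized when the group
#'   has several components), `regimen` (the matching regimen label) and
#'   the four membership flags.
#' @export
treatment_groups <- function() {
  regs <- filter(enumerate_regimens(), .data$n_components >= 1)
  regs$group <- ifelse(regs$n_components > 1,
                       paste0("(", regs$label, ")"), regs$label)
  select(regs, "group", regimen = "label", "cx", "v", "ai", "ar")
}

#' Bliss combination-index matrix over treatment-group pairs
#'
#' Builds the symmetric matrix of Bliss indexes for every ordered pair of
#' disjoint treatment groups, using one outcome type's inhibition
#' fractions; non-disjoint pairs (including the diagonal) are blank
#' (`NA`).
#'
#' @param outcomes Output of [predict_all_regimens()].
#' @param type Outcome type, `"I"` or `"II"`.
#' @return A `prostimm_ci_matrix`: a list with `matrix` (15 x 15, group
#'   labels as dimnames), `pairs` (long tibble `group_a`, `group_b`,
#'   `e_a`, `e_b`, `e_ab`, `ci`) and `type`.
#' @export
ci_matrix <- function(outcomes, type = c("I", "II")) {
  type <- match.arg(type)
  col <- paste0("inhibition_", type)
  groups <- treatment_groups()
  eff <- setNames(outcomes[[col]] / 100, outcomes$regimen)
  flags <- as.matrix(groups[, c("cx", "v", "ai", "ar")])
  n <- nrow(groups)
  m <- matrix(NA_real_, n, n, dimnames = list(groups$group, groups$group))
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || any(flags[i, ] & flags[j, ])) next
      uni <- flags[i, ] | flags[j, ]
      union_label <- regimen_label(c(cx = uni[["cx"]], v = uni[["v"]],
                                     ai = uni[["ai"]], ar = uni[["ar"]]))
      ci <- suppressWarnings(
        bliss_ci(eff[[groups$regimen[i]]], eff[[groups$regimen[j]]],
                 max(eff[[union_label]], 0)))
      m[i, j] <- ci
      if (i < j) {
        pairs[[length(pairs) + 1]] <- tibble(
          group_a = groups$group[i], group_b = groups$group[j],
          e_a = eff[[groups$regimen[i]]], e_b = eff[[groups$regimen[j]]],
          e_ab = eff[[union_label]], ci = ci)
      }
    }
  }
  structure(list(matrix = m, pairs = list_rbind(pairs), type = type),
            class = "prostimm_ci_matrix")
}

#' @export
print.prostimm_ci_matrix <- function(x, ...) {
  cat("<Bliss CI matrix> outcome type", x$type, "-",
      sum(!is.na(x$pairs$ci)), "applicable pairs\n")
  print(utils::head(arrange(x$pairs, .data$ci), 5))
  invisible(x)
}

#' Per-component efficacy and synergy summary
#'
#' For each of the four treatment components: (a) the mean percent
#' inhibition over the 8 regimens containing it; (b) its unmixed synergy
#' index, the mean Bliss CI over the single-component group's matrix row;
#' (c) its mixed synergy index, the mean CI over all rows whose group
#' contains the component. Synergy means are restricted to synergistic
#' entries (CI < 1); when none exist the mean is `NA`.
#'
#' @param outcomes Output of [predict_all_regimens()].
#' @param cim A [ci_matrix()] (its outcome type determines which
#'   inhibition column is summarized).
#' @return A tibble: `component`, `mean_inhibition`, `synergy_unmixed`,
#'   `synergy_mixed`, `n_regimens`.
#' @export
component_summary <- function(outcomes, cim) {
  groups <- treatment_groups()
  flags <- as.matrix(groups[, c("cx", "v", "ai", "ar")])
  regs <- enumerate_regimens()
  col <- paste0("inhibition_", cim$type)
  syn_mean <- function(v) {
    v <- v[!is.na(v) & v < 1]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  purrr::map(seq_along(regimen_components), function(k) {
    comp <- regimen_components[k]
    contains <- regs[[tolower(comp)]]
    single_row <- cim$matrix[groups$group == comp, ]
    mixed_rows <- cim$matrix[flags[, k], , drop = FALSE]
    tibble(
      component = comp,
      mean_inhibition = mean(outcomes[[col]][match(regs$label[contains],
                                                   outcomes$regimen)]),
      synergy_unmixed = syn_mean(single_row),
      synergy_mixed = syn_mean(as.vector(mixed_rows)),
      n_regimens = sum(contains)
    )
  }) |> list_rbind()
}

#' Pearson correlation with p-value
#'
#' Product-moment correlation between two equally long vectors with the
#' standard two-sided test.
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Unpaired Student's t-test
#'
#' Pooled-variance two-sample t-test, one- or two-tailed. For the
#' one-tailed test the alternative is that the first group's mean is
#' greater.
#'
#' @param group_a,group_b Numeric vectors (length >= 2 each).
#' @param tails `"two"` (default) or `"one"`.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @export
t_test <- function(group_a, group_b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs >= 2 values.")
  }
  alt <- if (tails == "one") "greater" else "two.sided"
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE, alternative = alt)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value)
}
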
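#' Treatment regimens
#'
#' A regimen is any subset of the four basic treatments: castration
#' (`CX`, androgen-deprivation therapy), tumor-cell vaccination (`V`),
#' IL-2 neutralization (`AI`) and Treg depletion (`AR`). The empty subset
#' is the sham-castrated, untreated control and is labelled `SX`.
#' Combining the four treatments with the control gives 16 regimens in
#' total, of which 7 were carried out in the mouse experiments the model
#' is calibrated against.
#'
#' @param cx,v,ai,ar Logical flags: is the component part of the regimen?
#' @return A `prostimm_regimen` object (a named list with the four flags
#'   and a canonical `label`).
#' @examples
#' regimen(cx = TRUE, ar = TRUE)        # "CX + AR"
#' regimen()                            # the untreated control, "SX"
#' @export
regimen <- function(cx = FALSE, v = FALSE, ai = FALSE, ar = FALSE) {
  flags <- c(cx = isTRUE(cx), v = isTRUE(v), ai = isTRUE(ai), ar = isTRUE(ar))
  out <- c(as.list(flags), list(label = regimen_label(flags)))
  structure(out, class = "prostimm_regimen")
}

#' @export
print.prostimm_regimen <- function(x, ...) {
  cat("<regimen> ", x$label, "\n", sep = "")
  invisible(x)
}

regimen_components <- c("CX", "V", "AI", "AR")

regimen_label <- function(flags) {
  on <- regimen_components[c(flags[["cx"]], flags[["v"]], flags[["ai"]], flags[["ar"]])]
  if (length(on) == 0) "SX" else paste(on, collapse = " + ")
}

#' Parse a regimen label
#'
#' Accepts labels like `"CX + V + AR"`, `"CX+V+AR"`, `"SX"`, and the
#' experimental condition names `"SX + V"` (sham castration plus vaccine,
#' i.e. the regimen `V`). A leading `SX` component is dropped; component
#' order within the label is irrelevant.
#'
#' @param x A label string, or an existing `prostimm_regimen` (returned
#'   unchanged).
#' @return A `prostimm_regimen`.
#' @export
as_regimen <- function(x) {
  if (inherits(x, "prostimm_regimen")) return(x)
  if (!is.character(x) || length(x) != 1) {
    abort("`x` must be a regimen object or a single label string.")
  }
  parts <- strsplit(gsub(" ", "", x), "+", fixed = TRUE)[[1]]
  parts <- setdiff(toupper(parts), "SX")
  bad <- setdiff(parts, regimen_components)
  if (length(bad) > 0) {
    abort(paste0("Unknown treatment component(s): ", paste(bad, collapse = ", ")))
  }
  regimen(cx = "CX" %in% parts, v = "V" %in% parts,
          ai = "AI" %in% parts, ar = "AR" %in% parts)
}

#' Enumerate all 16 treatment regimens
#'
#' All subsets of \{CX, V, AI, AR\} in a deterministic canonical order:
#' the control `SX` first, then by number of components, lexicographically
#' by label within each size.
#'
#' @return A tibble with one row per regimen: `label`, the four flag
#'   columns `cx`, `v`, `ai`, `ar`, and `n_components`.
#' @examples
#' enumerate_regimens()
#' @export
enumerate_regimens <- function() {
  grid <- expand.grid(ar = c(FALSE, TRUE), ai = c(FALSE, TRUE),
                      v = c(FALSE, TRUE), cx = c(FALSE, TRUE))
  tbl <- tibble(
    label = vapply(seq_len(nrow(grid)), function(i) {
      regimen_label(c(cx = grid$cx[i], v = grid$v[i], ai = grid$ai[i], ar = grid$ar[i]))
    }, character(1)),
    cx = grid$cx, v = grid$v, ai = grid$ai, ar = grid$ar,
    n_components = grid$cx + grid$v + grid$ai + grid$ar
  )
  arrange(tbl, .data$n_components, .data$label)
}

#' The seven experimental treatment conditions
#'
#' The conditions under which the mouse experiments were run, in the
#' conventional order. `SX + V` denotes sham castration plus vaccination
#' (the regimen `V`); the other names coincide with regimen labels.
#'
#' @return A character vector of length 7.
#' @export
experimental_conditions <- function() {
  c("SX", "CX", "CX + AI", "CX + AR", "SX + V", "CX + V", "CX + V + AR")
}
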
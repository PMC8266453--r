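#' Count Lipinski rule-of-five violations
#'
#' Lipinski's rule of five flags a compound as unlikely to be orally
#' bioavailable when it violates any of: molecular weight > 500 g/mol,
#' logP > 5, more than 5 hydrogen-bond donors, or more than 10
#' hydrogen-bond acceptors.  This returns the number of violated
#' conditions (0--4) per compound.
#'
#' @param compounds data frame with numeric columns `mw`, `hbd`, `hba`,
#'   `logp` (one row per compound; a `compound_id` column is used in error
#'   messages when present).
#' @return integer vector of violation counts, one per row.
#' @examples
#' count_lipinski_violations(
#'   data.frame(mw = c(302.3, 610.6), hbd = c(5, 8),
#'              hba = c(7, 15), logp = c(1.99, -1.16)))
#' @export
count_lipinski_violations <- function(compounds) {
  needed <- c("mw", "hbd", "hba", "logp")
  missing_cols <- setdiff(needed, names(compounds))
  if (length(missing_cols) > 0L) {
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in needed) {
    bad <- which(is.na(compounds[[col]]))
    if (length(bad) > 0L) {
      id <- if ("compound_id" %in% names(compounds)) {
        compounds$compound_id[bad[1L]]
      } else {
        paste0("row ", bad[1L])
      }
      stop("missing descriptor '", col, "' for compound ", id)
    }
  }
  stopifnot(all(compounds$mw > 0), all(compounds$hbd >= 0),
            all(compounds$hba >= 0))
  as.integer((compounds$mw > 500) + (compounds$logp > 5) +
             (compounds$hbd > 5) + (compounds$hba > 10))
}

#' Lipinski conformity from a violation count
#'
#' The strict reading of "conforms to the rule of five" allows no
#' violation (`max_violations = 0`, the default); the classic textbook
#' reading tolerates one (`max_violations = 1`).
#'
#' @param violations integer vector in `[0, 4]`.
#' @param max_violations 0 or 1.
#' @return logical vector.
#' @export
lipinski_conformity <- function(violations, max_violations = 0L) {
  stopifnot(all(violations >= 0L), all(violations <= 4L),
            length(max_violations) == 1L, max_violations %in% c(0L, 1L))
  violations <= max_violations
}

#' BOILED-Egg human-intestinal-absorption ellipse
#'
#' The BOILED-Egg model (Daina & Zoete 2016) classifies gastrointestinal
#' absorption as high when a compound's (TPSA, WLOGP) point falls inside
#' the "egg white", an ellipse fitted to well-absorbed drugs in the
#' TPSA--WLOGP plane.  Defaults are the published white-ellipse
#' parameters: centre (71.051 A^2, 2.292), semi-axes 71.0405 and 4.370,
#' rotated -1.031325 degrees.
#'
#' @param cx,cy ellipse centre (TPSA in A^2, WLOGP dimensionless).
#' @param a,b semi-axis lengths along the rotated TPSA and WLOGP axes.
#' @param theta_deg rotation angle in degrees.
#' @return a list of class `gi_ellipse`.
#' @export
gi_ellipse <- function(cx = 71.051, cy = 2.292, a = 142.081 / 2,
                       b = 8.740 / 2, theta_deg = -1.031325) {
  stopifnot(a > 0, b > 0)
  structure(list(cx = cx, cy = cy, a = a, b = b, theta_deg = theta_deg),
            class = "gi_ellipse")
}

# Point-in-ellipse test; boundary counts as inside.
in_ellipse <- function(tpsa, wlogp, ellipse) {
  th <- ellipse$theta_deg * pi / 180
  dx <- tpsa - ellipse$cx
  dy <- wlogp - ellipse$cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  (u / ellipse$a)^2 + (v / ellipse$b)^2 <= 1 + 1e-9
}

#' Classify gastrointestinal absorption
#'
#' Returns the precomputed class when the input carries one (column
#' `gi_class`, values `"high"`/`"low"`, e.g. exported from SwissADME);
#' otherwise evaluates the BOILED-Egg ellipse on the `tpsa` and `wlogp`
#' columns.  A compound with neither a precomputed class nor both
#' descriptors is an error — absorption is never defaulted.
#'
#' @param compounds data frame with `gi_class` and/or `tpsa` + `wlogp`.
#' @param ellipse a [gi_ellipse()].
#' @return character vector, `"high"` or `"low"`, one per row.
#' @export
classify_gi <- function(compounds, ellipse = gi_ellipse()) {
  n <- nrow(compounds)
  pre <- if ("gi_class" %in% names(compounds)) {
    as.character(compounds$gi_class)
  } else {
    rep(NA_character_, n)
  }
  pre[!is.na(pre) & !nzchar(pre)] <- NA_character_
  bad_class <- !is.na(pre) & !pre %in% c("high", "low")
  if (any(bad_class)) {
    stop("gi_class must be 'high' or 'low', got: ",
         paste(unique(pre[bad_class]), collapse = ", "))
  }
  need <- is.na(pre)
  if (any(need)) {
    has_xy <- c("tpsa", "wlogp") %in% names(compounds)
    tpsa <- if (has_xy[1L]) compounds$tpsa else rep(NA_real_, n)
    wlogp <- if (has_xy[2L]) compounds$wlogp else rep(NA_real_, n)
    no_xy <- need & (is.na(tpsa) | is.na(wlogp))
    if (any(no_xy)) {
      id <- if ("compound_id" %in% names(compounds)) {
        compounds$compound_id[which(no_xy)[1L]]
      } else {
        paste0("row ", which(no_xy)[1L])
      }
      stop("compound ", id,
           " has neither a precomputed gi_class nor (tpsa, wlogp)")
    }
    pre[need] <- ifelse(in_ellipse(tpsa[need], wlogp[need], ellipse),
                        "high", "low")
  }
  pre
}

#' Screen compounds by ADME criteria
#'
#' Two-criterion active-compound filter: a compound is retained when it
#' conforms to Lipinski's rule of five and has high predicted
#' gastrointestinal absorption.  Compounds failing either filter can be
#' added back on literature evidence of bioactivity, via the `overrides`
#' id list or a logical `literature_override` column.
#'
#' @param compounds data frame with columns `compound_id`, `mw`, `hbd`,
#'   `hba`, `logp` and either `gi_class` or `tpsa` + `wlogp`; optional
#'   logical `literature_override`.
#' @param max_violations Lipinski tolerance, 0 (strict, default) or 1.
#' @param overrides character vector of compound ids to retain regardless
#'   of descriptors (unioned with the `literature_override` column).
#' @param ellipse a [gi_ellipse()] used when `gi_class` is absent.
#' @return data frame of class `screening_decisions` with one row per
#'   input compound, input order preserved: `compound_id`,
#'   `lipinski_violations`, `lipinski_pass`, `gi_class`, `retained`,
#'   `reason` (`passed_filters` / `literature_override` / `excluded`).
#' @examples
#' tbl <- data.frame(compound_id = c("C1", "C2"),
#'                   mw = c(300, 620), hbd = c(2, 8), hba = c(4, 14),
#'                   logp = c(2.1, -1.0), gi_class = c("high", "low"))
#' screen_compounds(tbl, overrides = "C2")
#' @export
screen_compounds <- function(compounds, max_violations = 0L,
                             overrides = NULL, ellipse = gi_ellipse()) {
  ids <- as.character(compounds$compound_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate compound_id(s): ", paste(dup, collapse = ", "))
  }
  viol <- count_lipinski_violations(compounds)
  pass <- lipinski_conformity(viol, max_violations)
  gi <- classify_gi(compounds, ellipse)
  override <- ids %in% overrides
  if ("literature_override" %in% names(compounds)) {
    override <- override | as_logical_strict(compounds$literature_override)
  }
  filters_ok <- pass & gi == "high"
  retained <- filters_ok | override
  reason <- ifelse(filters_ok, "passed_filters",
                   ifelse(override, "literature_override", "excluded"))
  structure(
    data.frame(compound_id = ids, lipinski_violations = viol,
               lipinski_pass = pass, gi_class = gi, retained = retained,
               reason = reason, stringsAsFactors = FALSE),
    class = c("screening_decisions", "data.frame"))
}

as_logical_strict <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(trimws(as.character(x)))
  x %in% c("true", "t", "1", "yes")
}

#' @export
print.screening_decisions <- function(x, ...) {
  cat("ADME screening:", nrow(x), "compounds,", sum(x$retained),
      "retained (", sum(x$reason == "literature_override"),
      "by literature override )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Summarise a screening run
#'
#' @param object a `screening_decisions` data frame.
#' @param ... unused.
#' @return list with `n_input`, `n_retained`, `n_override`.
#' @export
summary.screening_decisions <- function(object, ...) {
  list(n_input = nrow(object),
       n_retained = sum(object$retained),
       n_override = sum(object$reason == "literature_override"))
}
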
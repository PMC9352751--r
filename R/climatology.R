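#' Multi-year NDVI climatology stack
#'
#' Holds, for each week-of-year slot 1..53 (or biweekly slot 1..27), every
#' year's NDVI composite for that slot, together with the per-pixel derived
#' reference fields min, max, mean and median computed over the stored
#' years. 53 weekly slots exist regardless of whether a particular year has
#' 52 or 53 weeks, matching the fixed file count of the operational
#' multi-year products. Per-year grids are retained in full — exact medians
#' cannot be maintained from running summaries — and the derived fields of a
#' slot are recomputed whenever the slot changes, so an incremental
#' [climatology_update()] is always bitwise identical to a rebuild.
#'
#' @param composites List of [index_grid()] NDVI composites, each carrying a
#'   weekly or biweekly [composite_period()].
#' @return An object of class `climatology_stack` with elements `cadence`,
#'   `geometry`, `weeks` (per slot, a year-named list of value matrices) and
#'   `derived` (per slot, matrices `min`, `max`, `mean`, `median`).
#' @seealso [climatology_update()], [reference_for()], [previous_year()]
#' @export
climatology_build <- function(composites) {
  if (!length(composites)) stop("no composites supplied", call. = FALSE)
  g1 <- composites[[1]]
  stopifnot(inherits(g1, "index_grid"))
  cadence <- g1$period$cadence
  if (!cadence %in% c("weekly", "biweekly")) {
    stop("climatologies are built from weekly or biweekly composites",
         call. = FALSE)
  }
  n_slots <- if (cadence == "weekly") 53L else 27L
  stack <- structure(
    list(cadence = cadence, geometry = g1$geometry,
         weeks = rep(list(list()), n_slots),
         derived = rep(list(NULL), n_slots)),
    class = "climatology_stack")
  for (g in composites) {
    stack <- insert_composite(stack, g, recompute = FALSE)
  }
  touched <- which(vapply(stack$weeks, function(w) length(w) > 0L, TRUE))
  for (k in touched) stack$derived[[k]] <- derive_slot(stack$weeks[[k]])
  stack
}

#' @export
print.climatology_stack <- function(x, ...) {
  yrs <- sort(unique(unlist(lapply(x$weeks, names))))
  filled <- sum(vapply(x$weeks, function(w) length(w) > 0L, TRUE))
  cat(sprintf("<climatology_stack> %s, %d x %d px, %d/%d slots filled, years %s\n",
              x$cadence, x$geometry$n_rows, x$geometry$n_cols, filled,
              length(x$weeks),
              if (length(yrs)) paste(range(yrs), collapse = "..") else "-"))
  invisible(x)
}

insert_composite <- function(stack, g, recompute = TRUE) {
  stopifnot(inherits(g, "index_grid"), g$kind == "NDVI",
            inherits(g$period, "composite_period"))
  if (!identical(g$period$cadence, stack$cadence)) {
    stop(sprintf("stack holds %s composites, got %s", stack$cadence,
                 g$period$cadence), call. = FALSE)
  }
  stop_if_geometry_mismatch(stack$geometry, g$geometry, "climatology grids")
  k <- g$period$week
  if (k < 1L || k > length(stack$weeks)) {
    stop(sprintf("slot %d outside 1..%d", k, length(stack$weeks)),
         call. = FALSE)
  }
  key <- as.character(g$period$year)
  existing <- stack$weeks[[k]][[key]]
  if (!is.null(existing)) {
    if (identical(existing, g$values)) return(stack)  # nothing to do
    message(sprintf("replacing existing composite for year %s, slot %d",
                    key, k))
  }
  stack$weeks[[k]][[key]] <- g$values
  if (recompute) stack$derived[[k]] <- derive_slot(stack$weeks[[k]])
  stack
}

# per-pixel min/max/mean/median over the years of one slot
derive_slot <- function(year_grids) {
  if (!length(year_grids)) return(NULL)
  vals <- do.call(cbind, lapply(year_grids, as.vector))  # ncell x nyears
  n_ok <- rowSums(!is.na(vals))
  any_ok <- n_ok > 0L
  mn <- mx <- me <- md <- rep(NA_real_, nrow(vals))
  if (any(any_ok)) {
    v <- vals[any_ok, , drop = FALSE]
    mn[any_ok] <- do.call(pmin, c(asplit(v, 2), na.rm = TRUE))
    mx[any_ok] <- do.call(pmax, c(asplit(v, 2), na.rm = TRUE))
    me[any_ok] <- rowSums(v, na.rm = TRUE) / n_ok[any_ok]
    md[any_ok] <- row_medians(v)
  }
  dm <- dim(year_grids[[1]])
  list(min = matrix(mn, dm[1], dm[2]), max = matrix(mx, dm[1], dm[2]),
       mean = matrix(me, dm[1], dm[2]), median = matrix(md, dm[1], dm[2]))
}

# rowwise median with NA removal; even counts average the two central values
row_medians <- function(v) {
  if (ncol(v) == 1L) return(v[, 1])
  if (!anyNA(v)) {
    s <- t(apply(v, 1L, sort.int, method = "quick"))
    n <- ncol(v)
    if (n %% 2L == 1L) s[, (n + 1L) %/% 2L]
    else (s[, n %/% 2L] + s[, n %/% 2L + 1L]) / 2
  } else {
    apply(v, 1L, stats::median, na.rm = TRUE)
  }
}

#' Insert a yearly composite into a climatology stack
#'
#' Adds (or, with a message, replaces) one year's composite in its slot and
#' recomputes that slot's derived fields, leaving the stack identical to a
#' full rebuild over the enlarged archive.
#'
#' @param stack A `climatology_stack` from [climatology_build()].
#' @param composite An [index_grid()] NDVI composite with a period.
#' @return The updated `climatology_stack`.
#' @export
climatology_update <- function(stack, composite) {
  stopifnot(inherits(stack, "climatology_stack"))
  insert_composite(stack, composite, recompute = TRUE)
}

#' Historical reference field for a period of year
#'
#' Returns the requested per-pixel statistic over the archived years of one
#' slot, restricted by the reference policy. The default policy admits all
#' years strictly before the current product year, so an in-progress year
#' never damps its own anomaly; set `include_current = TRUE` to admit it.
#'
#' @param stack A `climatology_stack`.
#' @param week Slot number (1..53 weekly, 1..27 biweekly).
#' @param stat One of `"min"`, `"max"`, `"mean"`, `"median"`.
#' @param year Current product year defining the policy cutoff; `NULL`
#'   admits every archived year.
#' @param include_current Admit the composite of `year` itself, if archived.
#' @return An [index_grid()] of kind `"NDVI"` (no dated period; attributes
#'   `"week"`, `"stat"` and `"years"` record its provenance).
#' @export
reference_for <- function(stack, week, stat = c("min", "max", "mean", "median"),
                          year = NULL, include_current = FALSE) {
  stopifnot(inherits(stack, "climatology_stack"))
  stat <- match.arg(stat)
  week <- as.integer(week)
  if (week < 1L || week > length(stack$weeks)) {
    stop(sprintf("slot %d outside 1..%d", week, length(stack$weeks)),
         call. = FALSE)
  }
  slot <- stack$weeks[[week]]
  yrs <- as.integer(names(slot))
  if (!is.null(year)) {
    keep <- if (include_current) yrs <= year else yrs < year
    slot <- slot[keep]
    yrs <- yrs[keep]
  }
  if (!length(slot)) {
    stop(sprintf("no reference years available for slot %d", week),
         call. = FALSE)
  }
  d <- if (is.null(year) || length(slot) == length(stack$weeks[[week]])) {
    stack$derived[[week]]  # cached derivation covers the full year set
  } else {
    derive_slot(slot)
  }
  out <- index_grid(d[[stat]], "NDVI", period = NULL,
                    geometry = stack$geometry)
  attr(out, "week") <- week
  attr(out, "stat") <- stat
  attr(out, "years") <- sort(yrs)
  out
}

#' Previous year's composite for a slot
#'
#' Looks up the composite of `year - 1` for the given slot, the reference
#' grid of the RVCI ratio. When `week` is 53 and the previous year has only
#' 52 weeks, the week-52 composite is returned instead (with a message).
#'
#' @param stack A `climatology_stack`.
#' @param year Current product year.
#' @param week Slot number.
#' @return An [index_grid()] of kind `"NDVI"` carrying the stored period.
#' @export
previous_year <- function(stack, year, week) {
  stopifnot(inherits(stack, "climatology_stack"))
  year <- as.integer(year)
  week <- as.integer(week)
  key <- as.character(year - 1L)
  vals <- stack$weeks[[week]][[key]]
  used_week <- week
  if (is.null(vals) && week == 53L && stack$cadence == "weekly" &&
      n_iso_weeks(year - 1L) == 52L) {
    vals <- stack$weeks[[52L]][[key]]
    used_week <- 52L
    if (!is.null(vals)) {
      message(sprintf("year %d has 52 weeks; using week 52 for week-53 RVCI",
                      year - 1L))
    }
  }
  if (is.null(vals)) {
    stop(sprintf("no composite archived for year %d, slot %d",
                 year - 1L, week), call. = FALSE)
  }
  per <- make_slot_period(year - 1L, used_week, stack$cadence)
  index_grid(vals, "NDVI", per, stack$geometry)
}

make_slot_period <- function(year, week, cadence) {
  if (cadence == "weekly") week_partition(year)[[week]]
  else biweekly_partition(year)[[week]]
}
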
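# Liquid-property readouts of called foci: shape (circularity), fusion-event
# tracking with intensity conservation, and condition-comparison statistics.

# Background-subtracted aperture photometry: sum inside a disc of radius
# `r_ap` around (cy, cx) minus `bg` per pixel. Stable to subpixel mask
# flicker, unlike threshold masks.
aperture_flux <- function(img, cy, cx, r_ap, bg) {
  ys <- max(1, floor(cy - r_ap)):min(nrow(img), ceiling(cy + r_ap))
  xs <- max(1, floor(cx - r_ap)):min(ncol(img), ceiling(cx + r_ap))
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  disc <- d2 <= r_ap^2
  sum(img[ys, xs][disc]) - bg * sum(disc)
}

# Nucleoplasmic background: median over the reference mask excluding discs
# of radius `r_excl` around the given spot centres.
nucleoplasm_bg <- function(img, mask, centres, r_excl) {
  sel <- mask
  for (p in centres) {
    ys <- max(1, floor(p[1] - r_excl)):min(nrow(img), ceiling(p[1] + r_excl))
    xs <- max(1, floor(p[2] - r_excl)):min(ncol(img), ceiling(p[2] + r_excl))
    d2 <- outer((ys - p[1])^2, (xs - p[2])^2, `+`)
    sel[ys, xs][d2 <= r_excl^2] <- FALSE
  }
  stats::median(img[sel])
}

# Fraction of a Gaussian spot's total flux (lateral sigma `sigma`) falling in
# a disc of radius `r_ap` whose centre is `d` away from the spot centre.
spill_fraction <- function(d, r_ap, sigma) {
  stats::pchisq((r_ap / sigma)^2, df = 2, ncp = (d / sigma)^2)
}

# Deblended fluxes of two mutually contaminating spots from their raw
# aperture sums: R_i = F_i + s * F_j with s the cross-spill fraction.
deblend_pair <- function(r1, r2, d, r_ap, sigma) {
  s <- spill_fraction(d, r_ap, sigma)
  if (s >= 0.9) return(c(NA_real_, NA_real_))
  c(r1 - s * r2, r2 - s * r1) / (1 - s^2)
}

#' Circularity of a spot mask
#'
#' `4 * pi * Area / Perimeter^2` on the 2D projected mask, clamped to at most
#' 1. A disc scores near 1; elongated structures score low. Scale-invariant
#' up to discretization.
#'
#' @param mask Logical matrix containing a single connected object of at
#'   least 4 pixels.
#' @return Circularity in (0, 1].
#' @export
circularity <- function(mask) {
  stopifnot(is.matrix(mask))
  if (is.numeric(mask)) mask <- mask > 0
  area <- sum(mask)
  if (area < 4) stop("degenerate mask: need area >= 4 px", call. = FALSE)
  feats <- EBImage::computeFeatures.shape(EBImage::Image(mask * 1L))
  a <- feats[1, "s.area"]; p <- feats[1, "s.perimeter"]
  if (p <= 0) stop("degenerate mask perimeter", call. = FALSE)
  min(1, 4 * pi * a / p^2)
}

#' Track a two-spot fusion event through a time series
#'
#' Frame-to-frame nearest-neighbour linking of detected spots with a maximum
#' step distance; a merge is declared at the first frame where both partner
#' tracks are claimed by a single detected spot. Individual and combined
#' background-subtracted integrated intensities are reported per frame (the
#' combined series is partner sum before the merge and the merged spot's
#' intensity after). Supply a bleach-corrected series for conservation
#' analysis.
#'
#' @param series An [image_stack()] over t (or `(ny, nx, nt)` array).
#' @param nucleus_mask Logical matrix restricting detection.
#' @param params A [detect_params()]; `max_step_px` defaults to 3 PSF sigma.
#' @param max_step_px Maximum per-frame displacement for linking, pixels.
#' @param max_lost_frames Consecutive undetected frames tolerated before a
#'   track is terminated with a flag.
#' @return A list of class `fusion_track`: `intensity` (data frame `frame`,
#'   `int_1`, `int_2`, `int_3`, `combined`), `positions`, `merge_frame`
#'   (1-based index or `NA`), `terminated_early`.
#' @export
track_fusion <- function(series, nucleus_mask, params = detect_params(),
                         max_step_px = 3 * params$psf_sigma_px,
                         max_lost_frames = 2L) {
  arr <- as_stack_array(series)
  stopifnot(length(dim(arr)) == 3L)
  nt <- dim(arr)[3]
  roi <- nucleus_roi(nucleus_mask, 1L)

  detect_frame <- function(t) detect_candidates(arr[, , t], roi, params)

  d1 <- detect_frame(1)
  if (nrow(d1) < 2)
    stop("need >= 2 detected spots in the first frame", call. = FALSE)
  d1 <- d1[order(-d1$integrated), ][1:2, ]
  pos <- list(`1` = c(d1$peak_y[1], d1$peak_x[1]),
              `2` = c(d1$peak_y[2], d1$peak_x[2]))
  sig <- params$psf_sigma_px
  r_ap <- 2.5 * sig
  r_excl <- 4 * sig
  pair_flux <- function(img) {
    bg <- nucleoplasm_bg(img, nucleus_mask, pos[c("1", "2")], r_excl)
    r1 <- aperture_flux(img, pos[["1"]][1], pos[["1"]][2], r_ap, bg)
    r2 <- aperture_flux(img, pos[["2"]][1], pos[["2"]][2], r_ap, bg)
    deblend_pair(r1, r2, sqrt(sum((pos[["1"]] - pos[["2"]])^2)), r_ap, sig)
  }
  merged_flux <- function(img, p) {
    bg <- nucleoplasm_bg(img, nucleus_mask, list(p), r_excl)
    aperture_flux(img, p[1], p[2], r_ap, bg)
  }
  ints <- matrix(NA_real_, nt, 3,
                 dimnames = list(NULL, c("int_1", "int_2", "int_3")))
  ints[1, 1:2] <- pair_flux(arr[, , 1])
  pos_rows <- list(data.frame(frame = 1L, spot = 1:2,
                              y_px = d1$y_px, x_px = d1$x_px))
  merge_frame <- NA_integer_
  lost <- c(0L, 0L)
  terminated <- FALSE

  for (t in 2:nt) {
    det <- detect_frame(t)
    merged <- !is.na(merge_frame)
    if (merged) {
      if (nrow(det) == 0) { lost[1] <- lost[1] + 1L } else {
        dd <- sqrt((det$peak_y - pos[["3"]][1])^2 + (det$peak_x - pos[["3"]][2])^2)
        j <- which.min(dd)
        if (dd[j] <= max_step_px) {
          pos[["3"]] <- c(det$peak_y[j], det$peak_x[j])
          ints[t, 3] <- merged_flux(arr[, , t], pos[["3"]])
          pos_rows[[length(pos_rows) + 1]] <-
            data.frame(frame = t, spot = 3L, y_px = det$peak_y[j],
                       x_px = det$peak_x[j])
          lost[1] <- 0L
        } else lost[1] <- lost[1] + 1L
      }
      if (lost[1] > max_lost_frames) { terminated <- TRUE; break }
      next
    }
    # pre-merge: greedy one-to-one assignment of the two tracks
    assign_ <- c(NA_integer_, NA_integer_)
    if (nrow(det) > 0) {
      dmat <- rbind(
        sqrt((det$peak_y - pos[["1"]][1])^2 + (det$peak_x - pos[["1"]][2])^2),
        sqrt((det$peak_y - pos[["2"]][1])^2 + (det$peak_x - pos[["2"]][2])^2))
      ord <- order(dmat)
      used_det <- logical(nrow(det))
      for (k in ord) {
        tr <- (k - 1) %% 2 + 1
        dj <- (k - 1) %/% 2 + 1
        if (dmat[tr, dj] > max_step_px) break
        if (is.na(assign_[tr]) && !used_det[dj]) {
          assign_[tr] <- dj; used_det[dj] <- TRUE
        }
      }
      # a still-unassigned track whose nearest in-range spot was claimed by
      # the partner -> the two tracks have coalesced into one detection
      for (tr in 1:2) {
        if (is.na(assign_[tr])) {
          j <- which.min(dmat[tr, ])
          if (length(j) && dmat[tr, j] <= max_step_px &&
              j == assign_[3 - tr]) {
            merge_frame <- t
          }
        }
      }
    }
    if (!is.na(merge_frame)) {
      j <- assign_[!is.na(assign_)][1]
      pos[["3"]] <- c(det$peak_y[j], det$peak_x[j])
      ints[t, 3] <- merged_flux(arr[, , t], pos[["3"]])
      pos_rows[[length(pos_rows) + 1]] <-
        data.frame(frame = t, spot = 3L, y_px = det$peak_y[j],
                   x_px = det$peak_x[j])
      lost <- c(0L, 0L)
      next
    }
    for (tr in 1:2) {
      if (!is.na(assign_[tr])) {
        j <- assign_[tr]
        pos[[as.character(tr)]] <- c(det$peak_y[j], det$peak_x[j])
        pos_rows[[length(pos_rows) + 1]] <-
          data.frame(frame = t, spot = tr, y_px = det$peak_y[j],
                     x_px = det$peak_x[j])
        lost[tr] <- 0L
      } else lost[tr] <- lost[tr] + 1L
    }
    ints[t, 1:2] <- pair_flux(arr[, , t])
    if (any(lost > max_lost_frames)) { terminated <- TRUE; break }
  }

  combined <- ifelse(is.na(ints[, 3]),
                     ints[, 1] + ints[, 2], ints[, 3])
  # the combined series is defined at every frame: carry the last observed
  # value over isolated detection dropouts
  for (t in seq_along(combined))
    if (is.na(combined[t]) && t > 1) combined[t] <- combined[t - 1]
  structure(list(
    intensity = data.frame(frame = seq_len(nt), int_1 = ints[, 1],
                           int_2 = ints[, 2], int_3 = ints[, 3],
                           combined = combined),
    positions = do.call(rbind, pos_rows),
    merge_frame = merge_frame,
    terminated_early = terminated), class = "fusion_track")
}

#' @export
print.fusion_track <- function(x, ...) {
  cat(sprintf("<fusion_track> %d frames, merge at %s%s\n",
              nrow(x$intensity),
              if (is.na(x$merge_frame)) "none" else x$merge_frame,
              if (x$terminated_early) " [terminated early]" else ""))
  invisible(x)
}

# --- condition comparisons --------------------------------------------------

#' Build a comparison arm from per-cell callsets
#' @param callsets A `foci_callsets` object.
#' @return List with `counts` (per cell) and `intensities` (per focus,
#'   background-subtracted integrated intensity).
#' @export
arm_from_callsets <- function(callsets) {
  counts <- foci_counts(callsets)$n_foci
  ints <- unlist(lapply(callsets, function(s)
    if (s$count > 0) s$calls$integrated else numeric(0)))
  list(counts = counts, intensities = as.numeric(ints))
}

# Pairwise Welch comparisons against the control arm with a Sidak-style
# multiplicity correction over the family (Dunnett-T3-type procedure: no
# pooled variance, Welch-Satterthwaite df per pair).
dunnett_t3 <- function(values, control) {
  others <- setdiff(names(values), control)
  k <- length(others)
  rows <- lapply(others, function(nm) {
    a <- values[[control]]; b <- values[[nm]]
    tt <- stats::t.test(b, a)   # Welch by default
    # Sidak-style family correction, numerically stable for tiny p
    p_adj <- max(tt$p.value, -expm1(k * log1p(-tt$p.value)))
    data.frame(comparison = paste(nm, "vs", control),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adj = min(1, p_adj))
  })
  do.call(rbind, rows)
}

#' Compare foci statistics between experimental arms
#'
#' Per-cell focus counts and pooled per-focus intensities are compared across
#' arms the way the figure panels are: two arms get a two-tailed Welch
#' t-test; three or more arms get a one-way ANOVA (Welch) followed by
#' Dunnett-T3-style pairwise comparisons against the designated control
#' (pairwise Welch tests with per-pair Satterthwaite degrees of freedom and a
#' multiplicity-corrected p-value). Arm summaries follow the mean +/- SEM
#' convention.
#'
#' @param arms Named list of arms; each arm is either a `foci_callsets`
#'   object or a list with `counts` (numeric, per cell) and optionally
#'   `intensities` (numeric, per focus).
#' @param control Name of the control arm (default: first).
#' @return A list of class `condition_summary`: `arms` (data frame of
#'   per-arm n/mean/SEM for counts and intensities), `tests` (data frame with
#'   `metric`, `comparison`, `statistic`, `df`, `p_raw`, `p_adj`, `method`),
#'   and `anova_p` (named vector, present for >= 3 arms).
#' @export
compare_conditions <- function(arms, control = names(arms)[1]) {
  stopifnot(is.list(arms), length(arms) >= 2, !is.null(names(arms)),
            control %in% names(arms))
  arms <- lapply(arms, function(a)
    if (inherits(a, "foci_callsets")) arm_from_callsets(a) else a)
  if (any(vapply(arms, function(a) length(a$counts) < 2, TRUE)))
    stop("each arm needs >= 2 cells", call. = FALSE)

  summ <- do.call(rbind, lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    ints <- a$intensities
    data.frame(arm = nm, n_cells = length(a$counts),
               count_mean = mean(a$counts),
               count_sem = stats::sd(a$counts) / sqrt(length(a$counts)),
               n_foci = length(ints),
               intensity_mean = if (length(ints)) mean(ints) else NA_real_,
               intensity_sem = if (length(ints) > 1)
                 stats::sd(ints) / sqrt(length(ints)) else NA_real_)
  }))

  metrics <- list(counts = lapply(arms, `[[`, "counts"))
  ints <- lapply(arms, `[[`, "intensities")
  if (all(vapply(ints, function(x) length(x) > 1, TRUE)))
    metrics$intensities <- ints

  tests <- list()
  anova_p <- c()
  for (metric in names(metrics)) {
    vals <- metrics[[metric]]
    if (length(arms) == 2) {
      tt <- stats::t.test(vals[[2]], vals[[1]])
      tests[[metric]] <- data.frame(
        metric = metric,
        comparison = paste(names(vals)[2], "vs", names(vals)[1]),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value, p_adj = tt$p.value,
        method = "Welch two-tailed t-test")
    } else {
      g <- factor(rep(names(vals), lengths(vals)), levels = names(vals))
      av <- stats::oneway.test(unlist(vals) ~ g)
      anova_p[metric] <- av$p.value
      dt <- dunnett_t3(vals, control)
      dt$metric <- metric
      dt$method <- "Dunnett T3 (pairwise Welch, corrected)"
      tests[[metric]] <- dt[, c("metric", "comparison", "statistic", "df",
                                "p_raw", "p_adj", "method")]
    }
  }
  structure(list(arms = summ, tests = do.call(rbind, tests),
                 anova_p = if (length(anova_p)) anova_p else NULL),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary>\n")
  print(x$arms, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$tests, row.names = FALSE, digits = 4)
  invisible(x)
}
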
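# T/R subunit classification, open/closed interface classification, trimer
# state timelines, and the dimer-species census used to map trajectories
# onto proposed nucleation pathways.
#
# Classification thresholds follow the reported operational definitions:
# a subunit is R when its inter-domain distance has dropped strictly more
# than 2.5 Angstrom below the T reference; an interface is closed above
# 1100 Angstrom^2 buried area and open below 1000 Angstrom^2. A T band
# (reduction <= 1 Angstrom) and an indeterminate band in between are added
# so mid-gap frames are not force-labelled.

#' Classify subunit T/R states from an inter-domain distance series
#'
#' @param series data.frame from [interdomain_distance()] (needs a
#'   `distance` column).
#' @param reference_t T-state reference distance in Angstrom; default the
#'   mean over the first 5 percent of frames (at least one frame).
#' @param r_threshold reduction beyond which the subunit is R (strict;
#'   default 2.5 Angstrom).
#' @param t_threshold reduction up to which the subunit is still T
#'   (default 1.0 Angstrom).
#' @return data.frame `frame`, `distance`, `reference_t`, `reduction`,
#'   `label` (`"T"`, `"R"`, `"indeterminate"`).
#' @export
classify_subunit <- function(series, reference_t = NULL, r_threshold = 2.5,
                             t_threshold = 1.0) {
  d <- series$distance
  if (is.null(reference_t)) {
    reference_t <- mean(d[seq_len(max(1L, floor(length(d) * 0.05)))])
  }
  if (!is.numeric(reference_t) || reference_t <= 0) {
    stop_ftsz("reference_t must be positive", class = "invalid_spec_error")
  }
  reduction <- reference_t - d
  label <- ifelse(reduction > r_threshold, "R",
                  ifelse(reduction <= t_threshold, "T", "indeterminate"))
  out <- data.frame(frame = series$frame, distance = d,
                    reference_t = reference_t, reduction = reduction,
                    label = label, stringsAsFactors = FALSE)
  attr(out, "subunit") <- attr(series, "subunit")
  out
}

#' Classify open/closed interfaces from a buried-area series
#'
#' @param series an `interface_series` (or data.frame with `buried_A2`).
#' @param closed_threshold closed above this (strict), Angstrom^2.
#' @param open_threshold open below this (strict), Angstrom^2.
#' @return data.frame `frame`, `buried_A2`, `label` (`"closed"`, `"open"`,
#'   `"intermediate"`).
#' @export
classify_interface <- function(series, closed_threshold = 1100,
                               open_threshold = 1000) {
  if (closed_threshold <= open_threshold) {
    stop_ftsz("closed_threshold must exceed open_threshold",
              class = "invalid_spec_error")
  }
  df <- if (inherits(series, "interface_series")) series$series else series
  v <- df$buried_A2
  label <- ifelse(v > closed_threshold, "closed",
                  ifelse(v < open_threshold, "open", "intermediate"))
  out <- data.frame(frame = df$frame, buried_A2 = v, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "interface") <- if (inherits(series, "interface_series")) {
    series$interface
  } else attr(series, "interface")
  out
}

#' Per-frame trimer state and interface strings
#'
#' State strings are ordered bottom-middle-top; an indeterminate member
#' renders as `"?"` at its position. Interface strings order bottom then
#' top with `c` (closed), `o` (open), `i` (intermediate).
#'
#' @param subunit_records list of [classify_subunit()] outputs ordered
#'   bottom to top.
#' @param interface_records list of [classify_interface()] outputs ordered
#'   bottom then top (optional).
#' @return data.frame `frame`, `state`, and `interfaces` when interface
#'   records are given.
#' @export
trimer_timeline <- function(subunit_records, interface_records = NULL) {
  nf <- vapply(subunit_records, nrow, integer(1))
  if (length(unique(nf)) != 1L) {
    stop_ftsz("subunit records cover different frame ranges",
              class = "invalid_spec_error")
  }
  letters_ <- lapply(subunit_records, function(r) {
    ifelse(r$label == "indeterminate", "?", r$label)
  })
  state <- do.call(paste, c(letters_, sep = "-"))
  out <- data.frame(frame = subunit_records[[1]]$frame, state = state,
                    stringsAsFactors = FALSE)
  if (!is.null(interface_records)) {
    nfi <- vapply(interface_records, nrow, integer(1))
    if (any(nfi != nf[1])) {
      stop_ftsz("interface records cover different frame ranges",
                class = "invalid_spec_error")
    }
    code <- lapply(interface_records, function(r) {
      unname(c(closed = "c", open = "o", intermediate = "i")[r$label])
    })
    out$interfaces <- do.call(paste, c(code, sep = "-"))
  }
  out
}

#' Dimer-species census over a trimer timeline
#'
#' Counts dimer species per position. The bottom dimer is the
#' (middle, bottom) pair and the top dimer the (top, middle) pair; species
#' letters are ordered upper-then-lower (so `"T-R"` at the bottom dimer
#' means middle T over bottom R, the middle-bottom convention). Frames
#' with an indeterminate member of a pair are excluded from that pair's
#' counts. Also reports each subunit's first switch away from its initial
#' state (the order of switching).
#'
#' @param timeline data.frame from [trimer_timeline()].
#' @return list of class `species_census`: `dimers` (data.frame
#'   `position`, `species`, `count`), `excluded` (per position),
#'   `states` (trimer-string frequency table), `first_switch` (per
#'   subunit position, frame of first label change, NA if none),
#'   `n_frames`.
#' @export
species_census <- function(timeline) {
  if (nrow(timeline) == 0L) {
    stop_ftsz("empty timeline", class = "invalid_spec_error")
  }
  parts <- strsplit(timeline$state, "-", fixed = TRUE)
  n_sub <- length(parts[[1]])
  mat <- do.call(rbind, parts)
  positions <- list(bottom = c(2L, 1L))
  if (n_sub >= 3L) positions$top <- c(n_sub, n_sub - 1L)
  species_levels <- c("T-T", "T-R", "R-T", "R-R")
  dimers <- list()
  excluded <- integer(0)
  for (pos in names(positions)) {
    up <- mat[, positions[[pos]][1]]
    lo <- mat[, positions[[pos]][2]]
    ok <- up != "?" & lo != "?"
    sp <- factor(paste(up[ok], lo[ok], sep = "-"), levels = species_levels)
    dimers[[pos]] <- data.frame(position = pos, species = species_levels,
                                count = as.integer(table(sp)),
                                stringsAsFactors = FALSE)
    excluded[pos] <- sum(!ok)
  }
  first_switch <- apply(mat, 2, function(col) {
    ch <- which(col != col[1] & col != "?")
    if (length(ch)) timeline$frame[ch[1]] else NA_integer_
  })
  structure(list(dimers = do.call(rbind, dimers), excluded = excluded,
                 states = table(timeline$state),
                 first_switch = first_switch, n_frames = nrow(timeline)),
            class = "species_census")
}

#' Modal twist angle per interface category
#'
#' Pools theta1 samples by (condition tag, interface openness) category —
#' e.g. GTP-IF1 for closed interfaces and GTP-IF2 for open interfaces of a
#' GTP-condition trajectory — and returns the histogram mode of each
#' category (1 degree bins, parabolic refinement over the peak bin and its
#' neighbours). Intermediate frames are excluded. Categories with fewer
#' than `min_samples` frames are reported as undersampled with `NA` mode.
#'
#' @param angle_records named list of angle series from
#'   [decompose_interface_rotation()], names `"bottom"` and/or `"top"`.
#' @param interface_records named list of [classify_interface()] outputs
#'   with matching names and frame ranges.
#' @param tag condition label (e.g. `"GTP"`).
#' @param bin_width histogram bin width, degrees.
#' @param min_samples undersampling threshold (default 10).
#' @return data.frame `category`, `n`, `modal_theta1`, `undersampled`.
#' @export
angle_peaks_by_interface <- function(angle_records, interface_records,
                                     tag = "GTP", bin_width = 1,
                                     min_samples = 10) {
  if (!identical(sort(names(angle_records)), sort(names(interface_records)))) {
    stop_ftsz("angle and interface records must cover the same interfaces",
              class = "invalid_spec_error")
  }
  samples <- list(IF1 = numeric(0), IF2 = numeric(0))
  for (nm in names(angle_records)) {
    a <- angle_records[[nm]]
    s <- interface_records[[nm]]
    if (nrow(a) != nrow(s)) {
      stop_ftsz("angle and interface series are incongruent for ", nm,
                class = "invalid_spec_error")
    }
    samples$IF1 <- c(samples$IF1, a$theta1[s$label == "closed"])
    samples$IF2 <- c(samples$IF2, a$theta1[s$label == "open"])
  }
  rows <- lapply(names(samples), function(cat) {
    v <- samples[[cat]]
    if (length(v) < min_samples) {
      return(data.frame(category = paste0(tag, "-", cat), n = length(v),
                        modal_theta1 = NA_real_, undersampled = TRUE))
    }
    data.frame(category = paste0(tag, "-", cat), n = length(v),
               modal_theta1 = histogram_mode(v, bin_width),
               undersampled = FALSE)
  })
  do.call(rbind, rows)
}

# histogram mode with parabolic (three-point) refinement
histogram_mode <- function(v, bin_width = 1) {
  edges <- seq(floor(min(v) / bin_width) * bin_width,
               ceiling(max(v) / bin_width) * bin_width + bin_width,
               by = bin_width)
  h <- graphics::hist(v, breaks = edges, plot = FALSE)
  i <- which.max(h$counts)
  center <- h$mids[i]
  if (i > 1L && i < length(h$counts)) {
    cl <- h$counts[i - 1L]; cm <- h$counts[i]; cr <- h$counts[i + 1L]
    denom <- cl - 2 * cm + cr
    if (denom < 0) center <- center + 0.5 * bin_width * (cl - cr) / denom
  }
  center
}
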
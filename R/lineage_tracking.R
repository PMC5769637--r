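#' Read and validate a cell-tracking table
#'
#' Tracking links cell ids across consecutive frames as a four-column
#' table: `frame_t`, `cell_id_t`, `frame_t1`, `cell_id_t1`. A cell linked
#' to exactly one successor persists; a cell linked to exactly two
#' successors is a candidate division. Cells linked to three or more
#' successors, and successors claimed by more than one predecessor, are
#' tracking anomalies: they are excluded and listed in the anomaly report.
#'
#' @param x path to a CSV with the four link columns, or a data frame.
#' @return a `lineage_map` list: `links` (clean rows), `divisions`
#'   (`frame_t`, `frame_t1`, `mother_id`, `daughter1_id`, `daughter2_id`),
#'   `persistence`, and `anomalies` (offending rows with a `reason`).
#' @export
read_tracking <- function(x) {
  links <- if (is.character(x)) utils::read.csv(x) else as.data.frame(x)
  need <- c("frame_t", "cell_id_t", "frame_t1", "cell_id_t1")
  if (!all(need %in% names(links)))
    stop("tracking table must have columns ", paste(need, collapse = ", "))
  links <- links[, need]
  key_m <- interaction(links$frame_t, links$cell_id_t, links$frame_t1,
                       drop = TRUE)
  kids <- table(key_m)
  key_d <- interaction(links$frame_t, links$frame_t1, links$cell_id_t1,
                       drop = TRUE)
  moms <- tapply(links$cell_id_t, key_d, function(v) length(unique(v)))
  bad_m <- names(kids)[kids > 2L]
  bad_d <- names(moms)[moms > 1L]
  anomalies <- links[key_m %in% bad_m | key_d %in% bad_d, , drop = FALSE]
  if (nrow(anomalies))
    anomalies$reason <- ifelse(key_m[key_m %in% bad_m | key_d %in% bad_d]
                               %in% bad_m,
                               "more than two daughters", "multiple mothers")
  clean <- links[!(key_m %in% bad_m | key_d %in% bad_d), , drop = FALSE]
  key_c <- interaction(clean$frame_t, clean$cell_id_t, clean$frame_t1,
                       drop = TRUE)
  nk <- table(key_c)
  div_keys <- names(nk)[nk == 2L]
  div_rows <- clean[key_c %in% div_keys, ]
  divisions <- if (nrow(div_rows)) {
    do.call(rbind, lapply(split(div_rows, droplevels(
      interaction(div_rows$frame_t, div_rows$cell_id_t, div_rows$frame_t1))),
      function(d) data.frame(frame_t = d$frame_t[1L],
                             frame_t1 = d$frame_t1[1L],
                             mother_id = d$cell_id_t[1L],
                             daughter1_id = min(d$cell_id_t1),
                             daughter2_id = max(d$cell_id_t1))))
  } else {
    data.frame(frame_t = integer(0), frame_t1 = integer(0),
               mother_id = integer(0), daughter1_id = integer(0),
               daughter2_id = integer(0))
  }
  rownames(divisions) <- NULL
  persistence <- clean[key_c %in% names(nk)[nk == 1L], ]
  rownames(persistence) <- NULL
  structure(list(links = clean, divisions = divisions,
                 persistence = persistence, anomalies = anomalies),
            class = "lineage_map")
}

#' @export
print.lineage_map <- function(x, ...) {
  cat("lineage_map:", nrow(x$persistence), "persistence links,",
      nrow(x$divisions), "candidate divisions,",
      nrow(x$anomalies), "anomalous rows\n")
  invisible(x)
}

#' Extract division events from tracked, analysed frames
#'
#' Combines a [read_tracking()] map with per-frame topology (frames
#' analysed by [analyze_frame()]) into division events carrying the
#' mother's pre-mitotic and the daughters' post-mitotic neighbour counts.
#' An event is `valid` only when the mother is neighbour-complete at frame
#' t and both daughters are neighbour-complete at frame t+1 (stricter than
#' strictly necessary, but guarantees every count entering the division
#' matrix is fully defined). Events in which a neighbour of the mother
#' also divided in the same interval are flagged `neighbor_division`: such
#' contamination broadens an empirical division matrix beyond the de facto
#' one, so both filtered and unfiltered summaries should be reported.
#'
#' @param frames named list of analysed `segmented_frame`s; names are the
#'   frame identifiers used in the tracking table.
#' @param map a `lineage_map`.
#' @return data frame with one row per candidate division: ids and
#'   neighbour counts of mother and daughters, `neighbor_division` flag,
#'   `valid` flag, and `reason` for invalid events.
#' @export
extract_division_events <- function(frames, map) {
  stopifnot(inherits(map, "lineage_map"))
  dv <- map$divisions
  out <- vector("list", nrow(dv))
  for (i in seq_len(nrow(dv))) {
    ft <- as.character(dv$frame_t[i]); ft1 <- as.character(dv$frame_t1[i])
    f0 <- frames[[ft]]; f1 <- frames[[ft1]]
    if (is.null(f0) || is.null(f1) || is.null(f0$cells) || is.null(f1$cells))
      stop("frames must be analysed segmented_frames named by frame id")
    m <- dv$mother_id[i]
    d1 <- dv$daughter1_id[i]; d2 <- dv$daughter2_id[i]
    row0 <- f0$cells[f0$cells$id == m, ]
    row1 <- f1$cells[f1$cells$id == d1, ]
    row2 <- f1$cells[f1$cells$id == d2, ]
    reason <- NA_character_
    if (nrow(row0) == 0L) reason <- "mother missing from frame t"
    else if (nrow(row1) == 0L || nrow(row2) == 0L)
      reason <- "daughter missing from frame t+1"
    else if (!row0$neighbour_complete)
      reason <- "mother not neighbour-complete"
    else if (!row1$neighbour_complete || !row2$neighbour_complete)
      reason <- "daughter not neighbour-complete"
    mothers_here <- dv$mother_id[dv$frame_t == dv$frame_t[i]]
    nb <- f0$adjacency[[as.character(m)]]
    out[[i]] <- data.frame(
      frame_t = dv$frame_t[i], frame_t1 = dv$frame_t1[i],
      mother_id = m,
      mother_n = if (nrow(row0)) row0$n else NA_integer_,
      daughter1_id = d1,
      daughter1_n = if (nrow(row1)) row1$n else NA_integer_,
      daughter2_id = d2,
      daughter2_n = if (nrow(row2)) row2$n else NA_integer_,
      neighbor_division = !is.null(nb) && any(nb %in% setdiff(mothers_here, m)),
      valid = is.na(reason), reason = reason)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(frame_t = integer(0), frame_t1 = integer(0),
                     mother_id = integer(0), mother_n = integer(0),
                     daughter1_id = integer(0), daughter1_n = integer(0),
                     daughter2_id = integer(0), daughter2_n = integer(0),
                     neighbor_division = logical(0), valid = logical(0),
                     reason = character(0))
  rownames(ev) <- NULL
  ev
}

#' Division matrix from tracked events
#'
#' Convenience wrapper: filters events from [extract_division_events()]
#' (valid only; optionally also dropping neighbour-division contaminated
#' ones) and estimates the empirical per-daughter division matrix.
#'
#' @param events data frame from [extract_division_events()] (or any data
#'   frame with `mother_n`, `daughter1_n`, `daughter2_n`).
#' @param drop_contaminated drop events flagged `neighbor_division`
#'   (default `FALSE`: report the matrix as observed, like tracked in vivo
#'   data).
#' @param n_max passed to [empirical_division_matrix()].
#' @return a `division_matrix`.
#' @export
events_to_matrix <- function(events, drop_contaminated = FALSE,
                             n_max = NULL) {
  if ("valid" %in% names(events)) events <- events[events$valid, ]
  if (drop_contaminated && "neighbor_division" %in% names(events))
    events <- events[!events$neighbor_division, ]
  empirical_division_matrix(events, n_max = n_max)
}
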
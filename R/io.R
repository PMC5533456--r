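# Plain-text readers/writers for the pipeline's tabular interchange formats.
# All CSVs are comma-separated UTF-8 with a header row; coordinates in um,
# times in minutes.

#' Write/read the traces table
#'
#' Long format: cell_id, t_min, area_um2, true_group (optional).
#' @param table data.frame as produced by [generate_traces()]`$table`.
#' @param path file path.
#' @return `read_traces_csv` returns a list of [cell_trace()] plus the raw
#'   table.
#' @export
write_traces_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "area_um2")
  if (!all(need %in% names(tab)))
    stopf("traces file lacks column(s): %s",
          paste(setdiff(need, names(tab)), collapse = ", "))
  ids <- unique(tab$cell_id)
  traces <- lapply(ids, function(id) {
    d <- tab[tab$cell_id == id, ]
    d <- d[order(d$t_min), ]
    cell_trace(id, d$t_min, d$area_um2)
  })
  list(traces = traces, table = tab)
}

#' Write/read a fold polyline as JSON
#'
#' @param fold a [fold_line()].
#' @param path file path.
#' @export
write_fold_json <- function(fold, path) {
  jsonlite::write_json(list(closed = fold$closed,
                            vertices = unname(fold$vertices)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_json
#' @export
read_fold_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fold_line(j$vertices, closed = isTRUE(j$closed))
}

#' Write/read the clones table
#'
#' Columns: clone_id, cell_id, x_um, y_um, stage.
#' @param clones list of [clone()] objects.
#' @param path file path.
#' @export
write_clones_csv <- function(clones, path) {
  tab <- do.call(rbind, lapply(clones, function(cl) {
    data.frame(clone_id = cl$clone_id,
               cell_id = seq_len(nrow(cl$cells)),
               x_um = cl$cells$x, y_um = cl$cells$y,
               stage = cl$stage, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clones_csv
#' @export
read_clones_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$clone_id), function(d)
    clone(d$clone_id[1L], d$stage[1L], data.frame(x = d$x_um, y = d$y_um)))
}

#' Write/read contour stacks as JSON
#'
#' @param stacks list of [contour_stack()] objects.
#' @param path file path.
#' @export
write_contours_json <- function(stacks, path) {
  jsonlite::write_json(lapply(stacks, function(s) {
    list(cell_id = s$cell_id, domain = s$domain,
         slices = Map(function(z, pg) list(z_um = z, polygon = unname(pg)),
                      s$z, s$polygons))
  }), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j, function(s) {
    z <- vapply(s$slices, function(sl) sl$z_um, numeric(1))
    polys <- lapply(s$slices, function(sl)
      do.call(rbind, lapply(sl$polygon, unlist)))
    contour_stack(s$cell_id, s$domain, z, polys)
  })
}

#' Write/read the tracks table
#'
#' Columns: track_id, t, x_um, y_um, group (optional).
#' @param tracks list of [cell_track()] objects.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  tab <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(track_id = tr$track_id, t = tr$t, x_um = tr$x, y_um = tr$y,
               group = tr$group, stringsAsFactors = FALSE)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$track_id), function(d) {
    d <- d[order(d$t), ]
    cell_track(d$track_id[1L], d$t, d$x_um, d$y_um,
               group = if ("group" %in% names(d)) d$group[1L] else NA_character_)
  })
}

#' Write/read a profile as long CSV
#'
#' Columns: pos_um, channel, intensity; background levels travel in a
#' sidecar attribute column-free JSON written next to it.
#' @param p a [profile_line()].
#' @param path file path (the background sidecar gets extension
#'   `.background.json`).
#' @export
write_profile_csv <- function(p, path) {
  tab <- do.call(rbind, lapply(colnames(p$intensities), function(ch)
    data.frame(pos_um = p$positions, channel = ch,
               intensity = p$intensities[, ch], stringsAsFactors = FALSE)))
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(as.list(p$background),
                       paste0(path, ".background.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bg <- unlist(jsonlite::read_json(paste0(path, ".background.json"),
                                   simplifyVector = TRUE))
  channels <- unique(tab$channel)
  pos <- sort(unique(tab$pos_um))
  m <- sapply(channels, function(ch) {
    d <- tab[tab$channel == ch, ]
    d$intensity[order(d$pos_um)]
  })
  colnames(m) <- channels
  profile_line(pos, m, bg)
}
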
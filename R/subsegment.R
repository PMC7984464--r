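#' Importance table for the 18 parotid subsegments
#'
#' Relative-importance values for the 3 x 3 x 2 grid of parotid subsegments
#' (cranio-caudal third x antero-posterior third x medial-lateral half),
#' together with the octant map assigning each spatial cell a rank S1..S18
#' (rank 1 = most important). Importance must be non-increasing in rank and
#' the octant map must be a bijection between the 18 cells and ranks 1..18.
#'
#' Cell coding: `cc_third` 1 = caudal (lowest z) .. 3 = cranial;
#' `ap_third` 1 = anterior (lowest y) .. 3 = posterior; `ml_half`
#' 1 = medial, 2 = lateral (anatomical, laterality is resolved by
#' [assign_ranks()]).
#'
#' @param table A data frame with columns `rank`, `cc_third`, `ap_third`,
#'   `ml_half`, `importance`.
#' @return A tibble of class `importance_table`.
#' @export
importance_table <- function(table) {
  tbl <- tibble::as_tibble(table)
  need <- c("rank", "cc_third", "ap_third", "ml_half", "importance")
  if (!all(need %in% names(tbl))) {
    rlang::abort(paste0("importance table needs columns: ",
                        paste(need, collapse = ", ")))
  }
  tbl <- dplyr::arrange(tbl, .data$rank)
  if (!identical(as.integer(tbl$rank), 1:18)) {
    rlang::abort("importance table must contain ranks 1..18 exactly once.")
  }
  cells <- paste(tbl$cc_third, tbl$ap_third, tbl$ml_half)
  if (anyDuplicated(cells) || !all(tbl$cc_third %in% 1:3) ||
      !all(tbl$ap_third %in% 1:3) || !all(tbl$ml_half %in% 1:2)) {
    rlang::abort("octant map must be a bijection between the 18 cells and ranks 1..18.")
  }
  if (any(tbl$importance < 0)) {
    rlang::abort("importance values must be non-negative.")
  }
  if (any(diff(tbl$importance) > 1e-9)) {
    rlang::abort("importance must be non-increasing in rank.")
  }
  class(tbl) <- c("importance_table", class(tbl))
  tbl
}

#' Synthetic default importance table
#'
#' The published per-rank importance values are not reproduced here; this
#' default is a clearly-labelled synthetic placeholder to be replaced with
#' published values for clinical use. It anchors the most important
#' subsegment at 3.85 times the homogeneous-gland expectation (the known
#' anchor for the caudal-anterior subsegment) and decays geometrically so
#' the least important rank has virtually no importance. The octant map
#' orders cells caudal before cranial, anterior before posterior, medial
#' before lateral, so rank 1 is the caudal-anterior-medial cell.
#'
#' @param decay Geometric decay ratio per rank (default 0.7).
#' @return An [importance_table()].
#' @export
importance_table_synthetic <- function(decay = 0.7) {
  grid <- expand.grid(ml_half = 1:2, ap_third = 1:3, cc_third = 1:3)
  grid <- grid[order(grid$cc_third, grid$ap_third, grid$ml_half), ]
  importance_table(tibble::tibble(
    rank = 1:18,
    cc_third = grid$cc_third,
    ap_third = grid$ap_third,
    ml_half = grid$ml_half,
    importance = 3.85 * decay^(0:17)
  ))
}

#' Read an importance table from JSON
#'
#' Expected shape: an array of 18 objects with fields `rank`, `octant`
#' (itself `{cc_third, ap_third, ml_half}`), and `importance`.
#'
#' @param path JSON file path.
#' @return An [importance_table()].
#' @export
read_importance_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, flatten = TRUE)
  names(raw) <- sub("^octant\\.", "", names(raw))
  importance_table(raw)
}

#' Write an importance table to JSON
#' @param table An [importance_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_importance_table <- function(table, path) {
  out <- lapply(seq_len(nrow(table)), function(i) {
    list(rank = table$rank[i],
         octant = list(cc_third = table$cc_third[i],
                       ap_third = table$ap_third[i],
                       ml_half = table$ml_half[i]),
         importance = table$importance[i])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Importance scaling factors I1..I18
#'
#' Per-rank scaling factors for proportional base plans: each rank's
#' importance divided by rank 1's, so I1 = 1 and the vector is monotone
#' non-increasing.
#'
#' @param table An [importance_table()].
#' @return Numeric vector of length 18 (rank order).
#' @export
scaling_factors <- function(table) {
  stopifnot(inherits(table, "importance_table"))
  imp <- table$importance[order(table$rank)]
  if (imp[1] <= 0) rlang::abort("importance of rank 1 must be positive.")
  imp / imp[1]
}

# is the voxel set a single 6-connected component? (BFS over a neighbor table)
is_single_component <- function(vox) {
  d <- dim(vox)
  lin <- which(vox)
  n <- length(lin)
  if (n <= 1) return(TRUE)
  idx <- array(0L, d)
  idx[lin] <- seq_len(n)
  ai <- arrayInd(lin, d)
  nb <- matrix(0L, n, 6)
  col <- 0L
  for (axis in 1:3) {
    for (step in c(-1L, 1L)) {
      col <- col + 1L
      ok <- ai[, axis] + step >= 1L & ai[, axis] + step <= d[axis]
      shifted <- ai[ok, , drop = FALSE]
      shifted[, axis] <- shifted[, axis] + step
      nb[ok, col] <- idx[shifted]
    }
  }
  visited <- logical(n)
  frontier <- 1L
  visited[1L] <- TRUE
  while (length(frontier)) {
    nxt <- unique(as.vector(nb[frontier, , drop = FALSE]))
    nxt <- nxt[nxt > 0L]
    nxt <- nxt[!visited[nxt]]
    visited[nxt] <- TRUE
    frontier <- nxt
  }
  all(visited)
}

# split a set of row indices into k near-equal contiguous chunks after
# ordering by `keys` (a list of tie-break vectors, primary first)
split_ordered <- function(rows, keys, k) {
  ord <- rows[do.call(order, keys)]
  n <- length(ord)
  bounds <- floor(n * (0:k) / k)
  lapply(seq_len(k), function(i) ord[(bounds[i] + 1L):bounds[i + 1L]])
}

#' Partition a gland mask into 18 equal-volume spatial cells
#'
#' Nested voxel-count quantile splits: cranio-caudal into 3 equal-count
#' slabs, each slab antero-posterior into 3, each of those medial-lateral
#' into 2, giving 18 cells whose voxel counts each lie within
#' `max(1, 0.02 * N/18)` of `N/18`. Boundary voxels go to the lower cell;
#' ties within a split plane are broken by sorting on the remaining axes in
#' (z, y, x) precedence, so the partition is deterministic.
#'
#' Cell labels are geometric (pre-ranking): label =
#' `(cc - 1) * 6 + (ap - 1) * 2 + ml` with `ml` ordered by ascending x.
#' Use [assign_ranks()] to relabel cells into importance ranks S1..S18.
#'
#' @param gland A non-empty [binary_mask()] (warns if not a single
#'   connected component).
#' @return A `parotid_labelmap`: list with `labels` (integer array, 0 =
#'   background), `grid`, `cells` (tibble mapping label to octant), and
#'   `ranked = FALSE`.
#' @export
partition_equal_volume <- function(gland) {
  stopifnot(inherits(gland, "binary_mask"))
  n <- sum(gland$voxels)
  if (n < 18) rlang::abort("gland mask has fewer than 18 voxels; cannot partition.")
  if (!is_single_component(gland$voxels)) {
    rlang::warn("gland mask is not a single connected component; partitioning anyway.")
  }
  d <- dim(gland$voxels)
  lin <- which(gland$voxels)
  ai <- arrayInd(lin, d)  # columns: x, y, z voxel indices
  rows <- seq_len(nrow(ai))
  labels <- array(0L, d)
  cells <- list()
  slabs <- split_ordered(rows, list(ai[rows, 3], ai[rows, 2], ai[rows, 1]), 3)
  for (cc in 1:3) {
    r1 <- slabs[[cc]]
    aps <- split_ordered(r1, list(ai[r1, 2], ai[r1, 3], ai[r1, 1]), 3)
    for (ap in 1:3) {
      r2 <- aps[[ap]]
      mls <- split_ordered(r2, list(ai[r2, 1], ai[r2, 3], ai[r2, 2]), 2)
      for (ml in 1:2) {
        lab <- (cc - 1L) * 6L + (ap - 1L) * 2L + ml
        labels[lin[mls[[ml]]]] <- lab
        cells[[lab]] <- tibble::tibble(label = lab, cc_third = cc,
                                       ap_third = ap, ml_half_geom = ml,
                                       n_voxels = length(mls[[ml]]))
      }
    }
  }
  structure(list(
    labels = labels,
    grid = grid_geometry(gland),
    cells = dplyr::bind_rows(cells),
    ranked = FALSE
  ), class = "parotid_labelmap")
}

#' @export
print.parotid_labelmap <- function(x, ...) {
  cat(sprintf("<parotid_labelmap> %s labels, %d voxels, %s\n",
              if (x$ranked) "rank (S1..S18)" else "spatial-cell",
              sum(x$labels > 0),
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Relabel spatial cells into importance ranks S1..S18
#'
#' Looks each geometric cell up in the table's octant map and relabels its
#' voxels with the mapped rank. For a left parotid the medial-lateral axis
#' is mirrored before lookup so that "medial" and "lateral" stay
#' anatomically consistent (medial = toward the midline x = 0). No voxel
#' moves between cells; only labels change.
#'
#' @param cells A `parotid_labelmap` from [partition_equal_volume()].
#' @param table An [importance_table()].
#' @param laterality `"right"` or `"left"`.
#' @return A ranked `parotid_labelmap` (label k = rank S_k).
#' @export
assign_ranks <- function(cells, table, laterality = c("right", "left")) {
  stopifnot(inherits(cells, "parotid_labelmap"), inherits(table, "importance_table"))
  laterality <- match.arg(laterality)
  if (isTRUE(cells$ranked)) rlang::abort("label map is already ranked.")
  if (nrow(cells$cells) != 18 || any(cells$cells$n_voxels == 0)) {
    rlang::abort("expected exactly 18 non-empty spatial cells.")
  }
  # geometric half 1 = lower x; right gland sits at x < 0, so its medial
  # (toward x = 0) side is the *upper*-x half
  anat_ml <- function(geom_half) {
    if (laterality == "right") 3L - geom_half else geom_half
  }
  key <- function(cc, ap, ml) paste(cc, ap, ml)
  lookup <- stats::setNames(table$rank,
                            key(table$cc_third, table$ap_third, table$ml_half))
  map <- integer(18)
  for (i in seq_len(18)) {
    ci <- cells$cells[i, ]
    rk <- lookup[[key(ci$cc_third, ci$ap_third, anat_ml(ci$ml_half_geom))]]
    map[ci$label] <- rk
  }
  labels <- cells$labels
  pos <- labels > 0L
  labels[pos] <- map[labels[pos]]
  cells_ranked <- cells$cells
  cells_ranked$rank <- map[cells_ranked$label]
  structure(list(
    labels = labels,
    grid = cells$grid,
    cells = dplyr::arrange(cells_ranked, .data$rank),
    ranked = TRUE
  ), class = "parotid_labelmap")
}

#' Read/write a label map as a single JSON file
#'
#' A compact, exact, text-based serialization of a `parotid_labelmap`:
#' grid geometry (origin/spacing/shape in mm), the `ranked` flag, the cell
#' table, and the label array run-length encoded in column-major order.
#' This is an internal interchange format (e.g. between CLI steps), not a
#' DICOM object.
#'
#' @param path JSON file path.
#' @return The label map for the reader; the path, invisibly, for the
#'   writer.
#' @export
read_labelmap <- function(path) {
  raw <- jsonlite::fromJSON(path)
  labels <- array(rep(as.integer(raw$rle$value), raw$rle$length),
                  dim = raw$geometry$shape)
  structure(list(
    labels = labels,
    grid = make_geometry(raw$geometry$origin, raw$geometry$spacing,
                         raw$geometry$shape),
    cells = tibble::as_tibble(raw$cells),
    ranked = isTRUE(raw$ranked)
  ), class = "parotid_labelmap")
}

#' @rdname read_labelmap
#' @param labelmap A `parotid_labelmap`.
#' @export
write_labelmap <- function(labelmap, path) {
  stopifnot(inherits(labelmap, "parotid_labelmap"))
  r <- rle(as.integer(labelmap$labels))
  g <- labelmap$grid
  out <- list(
    geometry = list(origin = g$origin, spacing = g$spacing, shape = g$shape),
    ranked = labelmap$ranked,
    cells = labelmap$cells,
    rle = list(value = r$values, length = r$lengths)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-rank voxel counts of a label map
#' @param labelmap A `parotid_labelmap`.
#' @return A tibble with columns `label` and `n_voxels` (all 18 labels).
#' @export
label_counts <- function(labelmap) {
  tab <- tabulate(labelmap$labels[labelmap$labels > 0L], nbins = 18)
  tibble::tibble(label = 1:18, n_voxels = tab)
}
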
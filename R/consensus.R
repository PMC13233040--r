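# Linking pairwise matches across all reader pairs into per-image consensus
# objects (the match matrix), the layered label-image representation, and
# ground-truth curation at a chosen agreement stringency.

# All retained pairwise matches on one image, as an edge list over
# (reader, call) nodes. Node ids are "reader\rcall_index".
pairwise_match_edges <- function(calls, image, readers, metric, threshold) {
  pairs <- reader_pairs(readers)
  edges <- purrr::pmap(pairs, function(reader_a, reader_b) {
    am <- agreement_matrix(calls, image, reader_a, reader_b, metric)
    mp <- suppress_nonmaximum(am, threshold)
    tibble::tibble(
      from = paste(reader_a, mp$call_a, sep = "\r"),
      to = paste(reader_b, mp$call_b, sep = "\r"),
      score = mp$score
    )
  }) |> dplyr::bind_rows()
  edges$eidx <- seq_len(nrow(edges))
  edges
}

node_ids <- function(calls, image, readers) {
  sub <- calls[calls$image_id == image & calls$reader_id %in% readers, ]
  sub <- sub[order(match(sub$reader_id, readers), sub$call_index), ]
  list(ids = paste(sub$reader_id, sub$call_index, sep = "\r"),
       reader = sub$reader_id, call_index = sub$call_index)
}

# Connected components of the match graph under the one-call-per-reader
# constraint. While any component holds two calls from the same reader
# (a transitive conflict, which the match matrix cannot represent), the
# lowest-score edge in that component is deleted (ties: earliest edge in
# pair-enumeration order) and components are recomputed.
link_components <- function(nodes, edges) {
  if (length(nodes$ids) == 0L) {
    return(list(membership = integer(0), n_dropped = 0L))
  }
  n_dropped <- 0L
  repeat {
    g <- igraph::graph_from_data_frame(
      edges[c("from", "to")], directed = FALSE,
      vertices = data.frame(name = nodes$ids)
    )
    memb <- igraph::components(g)$membership[nodes$ids]
    bad <- NULL
    for (comp in split(seq_along(nodes$ids), memb)) {
      if (anyDuplicated(nodes$reader[comp])) { bad <- comp; break }
    }
    if (is.null(bad)) {
      return(list(membership = as.integer(memb), n_dropped = n_dropped))
    }
    in_comp <- nodes$ids[bad]
    cand <- edges[edges$from %in% in_comp & edges$to %in% in_comp, ]
    drop <- cand$eidx[order(cand$score, cand$eidx)][1L]
    edges <- edges[edges$eidx != drop, ]
    n_dropped <- n_dropped + 1L
  }
}

#' Build the per-image match matrix
#'
#' Computes all `n(n-1)/2` pairwise agreement matrices for the readers in
#' `calls`, applies thresholded non-maximum suppression to each, and links
#' the retained matches into consensus objects: connected components of the
#' graph whose nodes are calls and whose edges are retained pairs. Each
#' object holds at most one call per reader; when transitive matching would
#' violate that, the weakest edge in the offending component is dropped and
#' linking is repeated (a warning reports how many edges were dropped).
#' Unmatched calls become singleton objects, so every call appears in
#' exactly one object.
#'
#' @param calls A calls table covering >= 2 readers.
#' @param image Image id to process.
#' @param metric Overlap metric, see [agreement_matrix()].
#' @param threshold Agreement threshold in (0, 1].
#' @param readers Optional reader subset (default: all readers in `calls`,
#'   in order of appearance).
#' @return An object of class `"match_matrix"`: a list with `image_id`,
#'   `readers`, `entries` (a tibble `object`, `reader_id`, `call_index`),
#'   `metric`, `threshold`. `tidy()` renders it as the familiar
#'   objects-by-readers table with blanks for readers who missed an object.
#' @export
build_match_matrix <- function(calls, image, metric = "mask_iou",
                               threshold = 0.5, readers = NULL) {
  readers <- readers %||% reader_ids(calls)
  if (length(readers) < 2L) stop("need >= 2 readers", call. = FALSE)
  edges <- pairwise_match_edges(calls, image, readers, metric, threshold)
  nodes <- node_ids(calls, image, readers)
  lk <- link_components(nodes, edges)
  if (lk$n_dropped > 0L) {
    message("image '", image, "': dropped ", lk$n_dropped,
            " transitive-conflict edge(s) to keep one call per reader ",
            "per object")
  }
  match_matrix_from_membership(nodes, lk$membership, image, readers, metric,
                               threshold)
}

match_matrix_from_membership <- function(nodes, memb, image, readers,
                                         metric, threshold) {
  if (length(memb) == 0L) {
    entries <- tibble::tibble(object = integer(), reader_id = character(),
                              call_index = integer())
  } else {
    # number objects by first appearance in reader-major node order
    obj <- match(memb, unique(memb))
    entries <- tibble::tibble(object = obj, reader_id = nodes$reader,
                              call_index = nodes$call_index)
    entries <- entries[order(entries$object, match(entries$reader_id, readers)), ]
  }
  structure(list(image_id = image, readers = readers, entries = entries,
                 metric = metric, threshold = threshold),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  k <- table(factor(table(x$entries$object),
                    levels = seq_along(x$readers)))
  cat("Match matrix for image '", x$image_id, "': ",
      length(unique(x$entries$object)), " objects x ",
      length(x$readers), " readers (", x$metric, " >= ", x$threshold,
      ")\n", sep = "")
  cat("objects by agreement level k:",
      paste(sprintf("k=%s:%d", names(k), as.integer(k)), collapse = " "),
      "\n")
  invisible(x)
}

# entries-per-object (k) for each object, named by object id
object_k <- function(mm) {
  tab <- table(mm$entries$object)
  stats::setNames(as.integer(tab), names(tab))
}

# Consensus mask of each object: the medoid member call (highest mean
# pairwise pixel IOU to the other members; ties by reader order). Singleton
# objects keep their own mask.
object_masks <- function(mm, calls) {
  sub <- calls[calls$image_id == mm$image_id &
                 calls$reader_id %in% mm$readers, ]
  lookup <- stats::setNames(sub$mask,
                            paste(sub$reader_id, sub$call_index, sep = "\r"))
  ids <- unique(mm$entries$object)
  purrr::map(ids, function(o) {
    e <- mm$entries[mm$entries$object == o, ]
    e <- e[order(match(e$reader_id, mm$readers)), ]
    masks <- lookup[paste(e$reader_id, e$call_index, sep = "\r")]
    if (any(vapply(masks, is.null, logical(1)))) {
      stop("consensus masks require masks on every member call",
           call. = FALSE)
    }
    if (length(masks) == 1L) return(masks[[1L]])
    mean_iou <- vapply(seq_along(masks), function(i) {
      mean(vapply(seq_along(masks)[-i], function(j) {
        mask_iou(masks[[i]], masks[[j]])
      }, double(1)))
    }, double(1))
    masks[[which.max(mean_iou)]]   # first max: reader-order tie-break
  }) |> stats::setNames(ids)
}

#' Layered consensus representation
#'
#' Renders a match matrix as a stack of `n_readers` label images: layer `k`
#' contains the consensus masks of the objects called by exactly `k`
#' readers. Labels (not binary masks) are stored so that adjacent objects
#' remain separable; within a layer labels run 1..n. Where two objects'
#' consensus masks overlap inside one layer, the later label wins.
#'
#' @param mm A [build_match_matrix()] result.
#' @param calls The calls table the match matrix was built from.
#' @param dims `c(height, width)` of the image.
#' @return An object of class `"layered_consensus"`: list with `image_id`,
#'   `dims`, and `layers` (a list of integer matrices, one per agreement
#'   level k).
#' @export
layered_representation <- function(mm, calls, dims) {
  dims <- as.integer(dims)
  n_readers <- length(mm$readers)
  k <- object_k(mm)
  masks <- object_masks(mm, calls)
  layers <- replicate(n_readers, matrix(0L, dims[1], dims[2]),
                      simplify = FALSE)
  counts <- integer(n_readers)
  for (o in names(masks)) {
    m <- masks[[o]]
    if (max(m[, 1L]) >= dims[1] || max(m[, 2L]) >= dims[2]) {
      stop("mask pixels outside the stated dims", call. = FALSE)
    }
    kk <- k[[o]]
    counts[kk] <- counts[kk] + 1L
    lin <- m[, 1L] + 1L + m[, 2L] * dims[1]
    layers[[kk]][lin] <- counts[kk]
  }
  structure(list(image_id = mm$image_id, dims = dims, layers = layers),
            class = "layered_consensus")
}

#' Write a layered consensus as a multi-page TIFF label stack
#'
#' One page per agreement level k, 16-bit labels.
#'
#' @param lc A [layered_representation()] result.
#' @param path Output `.tif` path.
#' @export
write_layered_tiff <- function(lc, path) {
  pages <- lapply(lc$layers, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write match matrices as JSON
#'
#' The serialized form stores the reader list and each object as a sparse
#' reader-to-call-index map, mirroring the objects-by-readers table with
#' blanks for readers who missed an object.
#'
#' @param mm A [build_match_matrix()] result.
#' @param path JSON path.
#' @export
write_match_matrix_json <- function(mm, path) {
  objects <- lapply(split(mm$entries, mm$entries$object), function(e) {
    stats::setNames(as.list(e$call_index), e$reader_id)
  })
  jsonlite::write_json(
    list(image_id = mm$image_id, readers = mm$readers,
         metric = mm$metric, threshold = mm$threshold,
         objects = unname(objects)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_match_matrix_json
#' @export
read_match_matrix_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- purrr::imap(doc$objects, function(o, i) {
    tibble::tibble(object = i, reader_id = names(o),
                   call_index = as.integer(unlist(o)))
  }) |> dplyr::bind_rows()
  structure(list(image_id = doc$image_id,
                 readers = as.character(unlist(doc$readers)),
                 entries = entries, metric = doc$metric,
                 threshold = doc$threshold),
            class = "match_matrix")
}

#' Curate a ground-truth set at a given agreement stringency
#'
#' Returns a synthetic "reader" whose calls are the consensus masks of all
#' match-matrix objects called by at least `min_calls` readers. With
#' `min_calls = 1` every consensus object is retained; with
#' `min_calls = n_readers` only objects every reader called survive.
#'
#' @param calls A calls table (>= 2 readers, masks required).
#' @param min_calls Integer in 1..n_readers.
#' @param metric,threshold Passed to [build_match_matrix()].
#' @param reader_id Reader id given to the curated set (default
#'   `"consensus"`).
#' @param images Optional image subset.
#' @return A calls table for the curated pseudo-reader (possibly empty for
#'   some images).
#' @export
curate_ground_truth <- function(calls, min_calls, metric = "mask_iou",
                                threshold = 0.5, reader_id = "consensus",
                                images = NULL) {
  n_readers <- length(reader_ids(calls))
  check_min_calls(min_calls, n_readers)
  images <- images %||% image_ids(calls)
  out <- purrr::map(images, function(img) {
    mm <- build_match_matrix(calls, img, metric, threshold)
    curate_from_match_matrix(mm, calls, min_calls, reader_id)
  })
  dplyr::bind_rows(out)
}

#' @rdname curate_ground_truth
#' @param mm A prebuilt [build_match_matrix()] result.
#' @export
curate_from_match_matrix <- function(mm, calls, min_calls,
                                     reader_id = "consensus") {
  check_min_calls(min_calls, length(mm$readers))
  k <- object_k(mm)
  keep <- names(k)[k >= min_calls]
  if (length(keep) == 0L) {
    return(tibble::tibble(reader_id = character(), image_id = character(),
                          call_index = integer(), mask = list(),
                          bbox = list()))
  }
  masks <- object_masks(mm, calls)[keep]
  extract_bounding_boxes(
    call_tbl(reader_id, mm$image_id, mask = unname(masks))
  )
}

check_min_calls <- function(min_calls, n_readers) {
  if (!is.numeric(min_calls) || min_calls < 1 || min_calls > n_readers) {
    stop("min_calls must lie in 1..", n_readers, call. = FALSE)
  }
}
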
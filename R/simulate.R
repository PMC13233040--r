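# Synthetic scenes of blob-like objects (stand-ins for cell nuclei) and
# simulated readers with controllable error profiles, so every pipeline
# stage is testable end to end without external data.

#' Generate a synthetic scene of blob-like objects
#'
#' Places `n_objects` randomly oriented ellipses (semi-axes drawn from
#' `size_range`) into an empty image by rejection sampling; objects are
#' pairwise disjoint at pixel level. Deterministic for a fixed seed.
#'
#' @param dims `c(height, width)` in pixels.
#' @param n_objects Number of objects to place.
#' @param size_range `c(min, max)` semi-axis length in pixels.
#' @param seed Integer seed.
#' @param image_id Image identifier.
#' @param max_attempts Placement attempts per object before giving up.
#' @return An object of class `"scene"`: list with `image_id`, `dims`,
#'   `masks` (list of (row, col) matrices), `size_range`.
#' @export
generate_scene <- function(dims = c(512L, 512L), n_objects = 20L,
                           size_range = c(5, 15), seed = 1L,
                           image_id = "img1", max_attempts = 200L) {
  dims <- as.integer(dims)
  masks <- withr::with_seed(seed, {
    lab <- matrix(FALSE, dims[1], dims[2])
    out <- vector("list", n_objects)
    for (i in seq_len(n_objects)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        m <- random_ellipse_mask(dims, size_range)
        if (is.null(m)) next
        lin <- m[, 1L] + 1L + m[, 2L] * dims[1]
        if (any(lab[lin])) next
        lab[lin] <- TRUE
        out[[i]] <- m
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place object ", i, " of ", n_objects, " in a ",
             dims[1], "x", dims[2], " image with sizes [",
             size_range[1], ", ", size_range[2], "] after ", max_attempts,
             " attempts", call. = FALSE)
      }
    }
    out
  })
  structure(list(image_id = image_id, dims = dims, masks = masks,
                 size_range = size_range), class = "scene")
}

# One random ellipse fully inside the image, as a pixel mask; NULL if the
# draw does not fit.
random_ellipse_mask <- function(dims, size_range) {
  a <- stats::runif(1, size_range[1], size_range[2])
  b <- stats::runif(1, size_range[1], size_range[2])
  theta <- stats::runif(1, 0, pi)
  rmax <- max(a, b)
  if (dims[1] <= 2 * rmax + 2 || dims[2] <= 2 * rmax + 2) return(NULL)
  cy <- stats::runif(1, rmax + 1, dims[1] - rmax - 2)
  cx <- stats::runif(1, rmax + 1, dims[2] - rmax - 2)
  ellipse_mask(cy, cx, a, b, theta, dims)
}

ellipse_mask <- function(cy, cx, a, b, theta, dims) {
  rmax <- ceiling(max(a, b))
  rows <- max(0L, floor(cy - rmax)):min(dims[1] - 1L, ceiling(cy + rmax))
  cols <- max(0L, floor(cx - rmax)):min(dims[2] - 1L, ceiling(cx + rmax))
  g <- expand.grid(row = rows, col = cols)
  dy <- g$row - cy; dx <- g$col - cx
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u * u + v * v <= 1
  if (!any(keep)) return(NULL)
  m <- cbind(row = g$row[keep], col = g$col[keep])
  storage.mode(m) <- "integer"
  m
}

#' Reader error profile
#'
#' Describes one simulated reader's error modes: the probability of missing
#' a true object (`miss_rate`, a false negative), the expected number of
#' spurious calls per image (`fp_rate`, a Poisson mean), the magnitude of
#' boundary jitter (`jitter_px`, per-object morphological dilation/erosion
#' radius drawn uniformly from `-jitter_px..jitter_px`), and the probability
#' of splitting a true object into two calls along a random chord
#' (`fragment_rate`), mimicking readers who delineate several objects where
#' another reader sees one.
#'
#' @param miss_rate,fragment_rate Probabilities in `[0, 1]`.
#' @param fp_rate Non-negative Poisson mean.
#' @param jitter_px Non-negative integer.
#' @return A list of class `"reader_profile"`.
#' @export
reader_profile <- function(miss_rate = 0.08, fp_rate = 3, jitter_px = 1L,
                           fragment_rate = 0.05) {
  stopifnot(miss_rate >= 0, miss_rate <= 1,
            fragment_rate >= 0, fragment_rate <= 1,
            fp_rate >= 0, jitter_px >= 0)
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_px = as.integer(jitter_px),
                 fragment_rate = fragment_rate),
            class = "reader_profile")
}

#' Simulate one reader annotating one scene
#'
#' Each scene object is independently missed with `miss_rate`; surviving
#' objects are jittered by a morphological dilation or erosion of random
#' radius up to `jitter_px` and fragmented into two calls with
#' `fragment_rate`. `Poisson(fp_rate)` spurious blobs are added away from
#' the true objects. Deterministic for a fixed seed.
#'
#' @param scene A [generate_scene()] result.
#' @param profile A [reader_profile()].
#' @param reader_id Reader identifier.
#' @param seed Integer seed.
#' @return A calls table for this reader on this image.
#' @export
simulate_reader <- function(scene, profile, reader_id = "R1", seed = 1L) {
  stopifnot(inherits(scene, "scene"), inherits(profile, "reader_profile"))
  dims <- scene$dims
  scene_keys <- unlist(lapply(scene$masks, px_key))
  masks <- withr::with_seed(seed, {
    out <- list()
    for (m in scene$masks) {
      if (stats::runif(1) < profile$miss_rate) next
      mm <- m
      if (profile$jitter_px > 0L) {
        r <- sample.int(2L * profile$jitter_px + 1L, 1L) -
          profile$jitter_px - 1L
        mm <- jitter_mask(mm, r, dims)
      }
      if (stats::runif(1) < profile$fragment_rate) {
        halves <- fragment_mask(mm)
        if (!is.null(halves)) {
          out <- c(out, halves)
          next
        }
      }
      out[[length(out) + 1L]] <- mm
    }
    n_fp <- stats::rpois(1, profile$fp_rate)
    for (i in seq_len(n_fp)) {
      for (a in seq_len(50L)) {
        fp <- random_ellipse_mask(dims, scene$size_range)
        if (is.null(fp)) next
        if (length(scene_keys) && any(px_key(fp) %in% scene_keys)) next
        out[[length(out) + 1L]] <- fp
        break
      }
    }
    out
  })
  if (length(masks) == 0L) {
    return(tibble::tibble(reader_id = character(), image_id = character(),
                          call_index = integer(), mask = list(),
                          bbox = list()))
  }
  extract_bounding_boxes(
    call_tbl(reader_id, scene$image_id, mask = masks)
  )
}

# Morphological dilation (r > 0) or erosion (r < 0) by a Euclidean disc of
# radius |r|, clipped to the image; erosion that would empty the mask leaves
# it unchanged.
jitter_mask <- function(mask, r, dims) {
  if (r == 0L) return(mask)
  offs <- disc_offsets(abs(r))
  keys <- px_key(mask)
  if (r > 0L) {
    grown <- unique(as.vector(outer(keys, offs, `+`)))
    m <- key_to_mask(grown)
    keep <- m[, 1L] >= 0L & m[, 1L] < dims[1] &
      m[, 2L] >= 0L & m[, 2L] < dims[2]
    m[keep, , drop = FALSE]
  } else {
    keep <- rep(TRUE, length(keys))
    for (o in offs) keep <- keep & ((keys + o) %in% keys)
    if (!any(keep)) return(mask)
    key_to_mask(keys[keep])
  }
}

disc_offsets <- function(r) {
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= r^2, ]
  g$dr * .KEY + g$dc
}

# Split along a random straight chord through the centroid; NULL when either
# half would be empty.
fragment_mask <- function(mask) {
  theta <- stats::runif(1, 0, pi)
  cy <- mean(mask[, 1L]); cx <- mean(mask[, 2L])
  side <- (mask[, 2L] - cx) * cos(theta) + (mask[, 1L] - cy) * sin(theta) > 0
  if (!any(side) || all(side)) return(NULL)
  list(mask[side, , drop = FALSE], mask[!side, , drop = FALSE])
}

#' Generate a multi-reader synthetic cohort
#'
#' Simulates `n_readers` readers independently annotating `n_images`
#' scenes. Substream seeds are derived per (image, reader) from the
#' top-level seed, so cohorts are reproducible, readers with equal profiles
#' are exchangeable in distribution, and adding a reader never perturbs the
#' other readers' annotations.
#'
#' Defaults mirror a typical nucleus-annotation study: 50 images of
#' 512x512 px with ~20 nuclei of radius 5-15 px each, five readers with a
#' moderate error profile.
#'
#' @param n_images,n_readers Cohort size.
#' @param profiles A single [reader_profile()] (recycled) or a list of one
#'   profile per reader.
#' @param seed Top-level integer seed.
#' @param dims,n_objects,size_range Scene parameters, see
#'   [generate_scene()].
#' @return A list of class `"reader_cohort"`: `scenes` (list of scenes),
#'   `calls` (combined calls table), `dims` (tibble `image_id`, `height`,
#'   `width`), `profiles`, `seed`.
#' @export
generate_cohort <- function(n_images = 50L, n_readers = 5L,
                            profiles = reader_profile(), seed = 1L,
                            dims = c(512L, 512L), n_objects = 20L,
                            size_range = c(5, 15)) {
  if (inherits(profiles, "reader_profile")) {
    profiles <- rep(list(profiles), n_readers)
  }
  if (length(profiles) != n_readers) {
    stop("need one profile per reader (got ", length(profiles), " for ",
         n_readers, " readers)", call. = FALSE)
  }
  readers <- sprintf("R%d", seq_len(n_readers))
  image_ids <- sprintf("img%03d", seq_len(n_images))
  scenes <- lapply(seq_len(n_images), function(i) {
    generate_scene(dims, n_objects, size_range,
                   seed = derive_seed(seed, i, 0L), image_id = image_ids[i])
  })
  calls <- purrr::map(seq_len(n_images), function(i) {
    purrr::map(seq_len(n_readers), function(j) {
      simulate_reader(scenes[[i]], profiles[[j]], readers[j],
                      seed = derive_seed(seed, i, j))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(list(
    scenes = scenes, calls = calls,
    dims = tibble::tibble(image_id = image_ids, height = dims[1],
                          width = dims[2]),
    profiles = stats::setNames(profiles, readers), seed = seed
  ), class = "reader_cohort")
}

#' Scene ground truth as a calls table
#'
#' Renders the true object masks of a scene (or list of scenes) as the
#' calls of a perfect pseudo-reader, handy as an error-free reference.
#'
#' @param scenes A scene or list of scenes.
#' @param reader_id Reader id for the pseudo-reader.
#' @return A calls table.
#' @export
scene_calls <- function(scenes, reader_id = "truth") {
  if (inherits(scenes, "scene")) scenes <- list(scenes)
  purrr::map(scenes, function(sc) {
    if (length(sc$masks) == 0L) {
      return(tibble::tibble(reader_id = character(), image_id = character(),
                            call_index = integer(), mask = list(),
                            bbox = list()))
    }
    extract_bounding_boxes(
      call_tbl(reader_id, sc$image_id, mask = sc$masks)
    )
  }) |> dplyr::bind_rows()
}
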
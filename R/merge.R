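# Peak-merge machinery. State lives in an environment:
#   members   list of member linear indices (1-based) per original id
#   area      pixel counts
#   max_value detection-domain maximum per peak
#   max_idx   1-based linear index of that maximum
#   cent      k x 3 matrix of plateau centroids (0-based x, y, z)
#   nb        per-peak named numeric vector: neighbour id -> saddle
#             (sparse symmetric adjacency; a merge costs O(degree))
#   alive     logical
#   hs, hn    highest saddle value and the neighbour across it

new_merge_state <- function(image, labels, candidates, saddles) {
  k <- nrow(candidates)
  members <- vector("list", k)
  idx <- which(labels > 0L)
  if (length(idx)) {
    sp <- split(idx, labels[idx])
    members[as.integer(names(sp))] <- sp
  }
  cent <- cbind(candidates$centroid_x, candidates$centroid_y,
                if ("centroid_z" %in% names(candidates))
                  candidates$centroid_z else rep(0, k))
  d3 <- img_dim3(image)
  max_idx <- with(candidates,
    x + d3[1L] * (y + d3[2L] * (if ("z" %in% names(candidates)) z else 0))
  ) + 1L
  st <- new.env(parent = emptyenv())
  st$members <- members
  st$area <- lengths(members)
  st$max_value <- candidates$value
  st$max_idx <- as.integer(max_idx)
  st$cent <- cent
  st$nb <- rep(list(numeric()), k)
  if (nrow(saddles)) {
    both <- data.frame(i = c(saddles$peak_id, saddles$neighbour_id),
                       j = c(saddles$neighbour_id, saddles$peak_id),
                       s = c(saddles$saddle_value, saddles$saddle_value))
    sp2 <- split(seq_len(nrow(both)), both$i)
    for (nm in names(sp2)) {
      rows <- sp2[[nm]]
      v <- both$s[rows]
      names(v) <- both$j[rows]
      st$nb[[as.integer(nm)]] <- v
    }
  }
  st$alive <- rep(TRUE, k)
  st$hs <- rep(NA_real_, k)
  st$hn <- rep(NA_integer_, k)
  st$image <- as.numeric(image)
  for (i in seq_len(k)) refresh_saddle(st, i)
  st
}

refresh_saddle <- function(st, i) {
  v <- st$nb[[i]]
  if (!length(v)) {
    st$hs[i] <- NA_real_
    st$hn[i] <- NA_integer_
  } else {
    m <- max(v)
    st$hs[i] <- m
    st$hn[i] <- min(as.integer(names(v)[v == m]))
  }
  invisible(st)
}

# absorb peak b into peak a, updating members, maxima and saddles
merge_pair <- function(st, b, a) {
  st$members[[a]] <- c(st$members[[a]], st$members[[b]])
  st$members[[b]] <- integer()
  st$area[a] <- st$area[a] + st$area[b]
  st$area[b] <- 0L
  if (st$max_value[b] > st$max_value[a] ||
      (st$max_value[b] == st$max_value[a] && st$max_idx[b] < st$max_idx[a])) {
    st$max_value[a] <- st$max_value[b]
    st$max_idx[a] <- st$max_idx[b]
    st$cent[a, ] <- st$cent[b, ]
  }
  ca <- as.character(a); cb <- as.character(b)
  m <- c(st$nb[[a]], st$nb[[b]])
  m <- m[!(names(m) %in% c(ca, cb))]
  if (length(m)) {
    nm <- names(m)
    first <- !duplicated(nm)
    res <- m[first]
    for (d in which(!first))
      res[nm[d]] <- max(res[[nm[d]]], m[[d]])
  } else res <- numeric()
  st$nb[[a]] <- res
  st$nb[[b]] <- numeric()
  st$alive[b] <- FALSE
  changed <- as.integer(names(res))
  for (j in changed) {
    vj <- st$nb[[j]]
    vj <- vj[!(names(vj) %in% c(ca, cb))]
    vj[[ca]] <- res[[as.character(j)]]
    st$nb[[j]] <- vj
    refresh_saddle(st, j)
  }
  refresh_saddle(st, a)
  invisible(st)
}

# pick the merge candidate per stage-specific ranking and merge it into
# the neighbour across its highest saddle; full rescan after every merge
run_merge_stage <- function(st, failing, ranking) {
  repeat {
    f <- failing(st)
    f <- f[st$alive[f] & !is.na(st$hs[f])]
    if (!length(f)) break
    r <- ranking(st, f)
    b <- f[order(r, f)[1L]]
    merge_pair(st, b, st$hn[b])
  }
  invisible(st)
}

#' Merge insignificant peaks
#'
#' Three-stage merging of expanded peaks, each stage repeatedly merging
#' the top-ranked failing peak into the neighbour across its highest
#' saddle and recomputing sizes and saddles before the next decision:
#' stage 1 merges peaks whose height above their highest saddle fails
#' `min_height_above_saddle` (peaks ranked by highest saddle,
#' descending); stage 2 merges peaks with `area < min_size` (smallest
#' first); stage 3 (only when `merge_above_saddle` is set) merges peaks
#' whose pixel count above their highest saddle is below `min_size`
#' (smallest count first). Isolated peaks (no saddle) never merge.
#'
#' @param image the image the labels were derived from.
#' @param labels integer label array from [expand_peaks()].
#' @param candidates the [find_candidate_maxima()] table for `labels`.
#' @param saddles saddle table from [compute_saddles()].
#' @param params a [foci_params()].
#' @param B background intensity used during expansion.
#' @return list with `labels` (relabelled array, original candidate ids
#'   kept for survivors) and `state` (internal merge state).
#' @export
merge_peaks <- function(image, labels, candidates, saddles, params, B) {
  st <- new_merge_state(image, labels, candidates, saddles)
  thr <- params$min_height_above_saddle
  if (thr > 0) {
    failing <- function(st) {
      i <- which(st$alive)
      t_i <- if (params$saddle_mode == "absolute") thr
             else thr * (st$max_value[i] - B)
      i[(st$max_value[i] - st$hs[i]) < t_i & !is.na(st$hs[i])]
    }
    run_merge_stage(st, failing, function(st, f) -st$hs[f])
  }
  if (params$min_size > 1L) {
    failing <- function(st) {
      i <- which(st$alive)
      i[st$area[i] < params$min_size]
    }
    run_merge_stage(st, failing, function(st, f) st$area[f])
  }
  if (params$merge_above_saddle && params$min_size > 1L) {
    count_above <- function(st, i)
      vapply(i, function(j)
        sum(st$image[st$members[[j]]] > st$hs[j]), numeric(1))
    failing <- function(st) {
      i <- which(st$alive & !is.na(st$hs))
      i[count_above(st, i) < params$min_size]
    }
    run_merge_stage(st, failing, function(st, f) count_above(st, f))
  }
  new_labels <- labels
  new_labels[] <- 0L
  for (i in which(st$alive)) new_labels[st$members[[i]]] <- i
  list(labels = new_labels, state = st)
}
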
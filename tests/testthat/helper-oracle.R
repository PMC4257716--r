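# Independent brute-force reference implementations, written with plain
# coordinate loops and full recomputation from the label grid after
# every merge. Used as oracles against the package's incremental
# implementations on small inputs.

o_neighbours <- function(i, nx, ny) {
  x <- (i - 1L) %% nx
  y <- (i - 1L) %/% nx
  out <- integer()
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    xx <- x + dx; yy <- y + dy
    if (xx >= 0L && xx < nx && yy >= 0L && yy < ny)
      out <- c(out, yy * nx + xx + 1L)
  }
  out
}

# connected equal-value components entirely above B with every adjacent
# pixel strictly lower; labelled in raster order of the first member
o_candidates <- function(img, B) {
  nx <- nrow(img); ny <- ncol(img)
  v <- as.numeric(img)
  n <- nx * ny
  lab <- integer(n)
  visited <- logical(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    comp <- i
    visited[i] <- TRUE
    front <- i
    while (length(front)) {
      nxt <- integer()
      for (p in front) for (q in o_neighbours(p, nx, ny))
        if (!visited[q] && v[q] == v[i]) {
          visited[q] <- TRUE
          nxt <- c(nxt, q)
        }
      comp <- c(comp, nxt)
      front <- nxt
    }
    if (!(v[i] > B)) next
    boundary_lower <- TRUE
    for (p in comp) for (q in o_neighbours(p, nx, ny))
      if (!(q %in% comp) && v[q] >= v[i]) boundary_lower <- FALSE
    if (boundary_lower) {
      k <- k + 1L
      lab[comp] <- k
    }
  }
  lab
}

# descending-intensity single-pass assignment, then per-peak floor trim
o_expand <- function(img, cand_lab, f, B) {
  nx <- nrow(img); ny <- ncol(img)
  v <- as.numeric(img)
  lab <- cand_lab
  ord <- order(-v, seq_along(v))
  for (i in ord) {
    if (lab[i] != 0L || !(v[i] > B)) next
    best <- 0L; bestv <- -Inf
    for (q in o_neighbours(i, nx, ny)) {
      if (lab[q] == 0L) next
      if (v[q] > bestv || (v[q] == bestv && lab[q] < best)) {
        bestv <- v[q]; best <- lab[q]
      }
    }
    if (best > 0L) lab[i] <- best
  }
  if (f > 0) {
    peak_max <- tapply(v[lab > 0L], lab[lab > 0L], max)
    for (i in which(lab > 0L & cand_lab == 0L)) {
      fl <- B + f * (peak_max[[as.character(lab[i])]] - B)
      if (v[i] <= fl) lab[i] <- 0L
    }
  }
  lab
}

o_saddles <- function(img, lab) {
  nx <- nrow(img); ny <- ncol(img)
  v <- as.numeric(img)
  out <- list()
  for (i in seq_along(v)) {
    if (lab[i] == 0L) next
    for (q in o_neighbours(i, nx, ny)) {
      if (q <= i || lab[q] == 0L || lab[q] == lab[i]) next
      a <- min(lab[i], lab[q]); b <- max(lab[i], lab[q])
      key <- paste(a, b)
      s <- min(v[i], v[q])
      if (is.null(out[[key]]) || s > out[[key]]$s)
        out[[key]] <- list(a = a, b = b, s = s)
    }
  }
  if (!length(out))
    return(data.frame(a = integer(), b = integer(), s = numeric()))
  do.call(rbind, lapply(out, function(e)
    data.frame(a = e$a, b = e$b, s = e$s)))
}

o_peak_stats <- function(img, lab) {
  v <- as.numeric(img)
  ids <- sort(unique(lab[lab > 0L]))
  do.call(rbind, lapply(ids, function(id) {
    mem <- which(lab == id)
    data.frame(id = id, area = length(mem), max = max(v[mem]),
               total = sum(v[mem]))
  }))
}

o_highest_saddle <- function(sad, id) {
  rows <- sad[sad$a == id | sad$b == id, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  m <- max(rows$s)
  rows <- rows[rows$s == m, , drop = FALSE]
  nbr <- ifelse(rows$a == id, rows$b, rows$a)
  list(s = m, nbr = min(nbr))
}

# merge stages with a full recomputation of stats and saddles from the
# label grid after every single merge
o_merge <- function(img, lab, B, min_size = 1, mhas = 0,
                    saddle_mode = "absolute",
                    merge_above_saddle = FALSE) {
  v <- as.numeric(img)
  one_pass <- function(lab, failing_pick) {
    repeat {
      st <- o_peak_stats(img, lab)
      if (is.null(st) || !nrow(st)) return(lab)
      sad <- o_saddles(img, lab)
      hs <- lapply(st$id, function(id) o_highest_saddle(sad, id))
      pick <- failing_pick(st, hs, lab)
      if (is.null(pick)) return(lab)
      lab[lab == pick$b] <- pick$a
    }
  }
  if (mhas > 0) {
    lab <- one_pass(lab, function(st, hs, lab) {
      cand <- NULL
      for (r in seq_len(nrow(st))) {
        h <- hs[[r]]
        if (is.null(h)) next
        thr <- if (saddle_mode == "absolute") mhas
               else mhas * (st$max[r] - B)
        if ((st$max[r] - h$s) < thr)
          cand <- rbind(cand, data.frame(id = st$id[r], key = -h$s,
                                         tgt = h$nbr))
      }
      if (is.null(cand)) return(NULL)
      cand <- cand[order(cand$key, cand$id), ]
      list(b = cand$id[1L], a = cand$tgt[1L])
    })
  }
  if (min_size > 1) {
    lab <- one_pass(lab, function(st, hs, lab) {
      cand <- NULL
      for (r in seq_len(nrow(st))) {
        if (is.null(hs[[r]])) next
        if (st$area[r] < min_size)
          cand <- rbind(cand, data.frame(id = st$id[r],
                                         key = st$area[r],
                                         tgt = hs[[r]]$nbr))
      }
      if (is.null(cand)) return(NULL)
      cand <- cand[order(cand$key, cand$id), ]
      list(b = cand$id[1L], a = cand$tgt[1L])
    })
  }
  if (merge_above_saddle && min_size > 1) {
    lab <- one_pass(lab, function(st, hs, lab) {
      cand <- NULL
      for (r in seq_len(nrow(st))) {
        h <- hs[[r]]
        if (is.null(h)) next
        mem <- which(lab == st$id[r])
        cnt <- sum(v[mem] > h$s)
        if (cnt < min_size)
          cand <- rbind(cand, data.frame(id = st$id[r], key = cnt,
                                         tgt = h$nbr))
      }
      if (is.null(cand)) return(NULL)
      cand <- cand[order(cand$key, cand$id), ]
      list(b = cand$id[1L], a = cand$tgt[1L])
    })
  }
  lab
}

# canonical description of a detection outcome: per-peak sorted member
# lists in final reporting order (descending max, ties by raster order
# of the maximum pixel)
o_canonical <- function(img, lab) {
  v <- as.numeric(img)
  st <- o_peak_stats(img, lab)
  if (is.null(st) || !nrow(st)) return(list())
  pos <- vapply(st$id, function(id) {
    mem <- which(lab == id)
    min(mem[v[mem] == max(v[mem])])
  }, numeric(1))
  ord <- order(-st$max, pos)
  lapply(st$id[ord], function(id) sort(which(lab == id)))
}

# full brute-force pipeline (no blur; absolute background)
o_find_foci <- function(img, B, f = 0, min_size = 1, mhas = 0,
                        saddle_mode = "absolute",
                        merge_above_saddle = FALSE, min_area = 0,
                        min_intensity = 0, min_height = 0) {
  cand <- o_candidates(img, B)
  lab <- o_expand(img, cand, f, B)
  lab <- o_merge(img, lab, B, min_size, mhas, saddle_mode,
                 merge_above_saddle)
  st <- o_peak_stats(img, lab)
  if (!is.null(st) && nrow(st)) {
    bad <- st$id[st$area < min_area | st$total < min_intensity |
                   (st$max - B) < min_height]
    lab[lab %in% bad] <- 0L
  }
  o_canonical(img, lab)
}

# exhaustive Otsu: histogram over 256 bins spanning min..max, trying
# every split and maximising between-class variance directly
o_otsu <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  width <- (hi - lo) / 256
  bin <- pmin(floor((v - lo) / width) + 1, 256)
  best_k <- NA; best_bcv <- -Inf
  for (k in 1:255) {
    left <- v[bin <= k]; right <- v[bin > k]
    if (!length(left) || !length(right)) next
    w0 <- length(left) / length(v)
    mid_of <- function(b) lo + (b - 0.5) * width
    mu0 <- mean(mid_of(bin[bin <= k]))
    mu1 <- mean(mid_of(bin[bin > k]))
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best_bcv + 1e-12) { best_bcv <- bcv; best_k <- k }
  }
  lo + best_k * width
}

# maximal matching by scanning the exhaustive edge list smallest first
o_match <- function(a, b, radius) {
  na <- nrow(a); nb <- nrow(b)
  cols <- intersect(c("x", "y", "z"), names(a))
  edges <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    d <- sqrt(sum((as.numeric(a[i, cols]) - as.numeric(b[j, cols]))^2))
    if (d <= radius)
      edges <- rbind(edges, data.frame(i = i, j = j, d = d))
  }
  if (is.null(edges)) return(data.frame(i = integer(), j = integer(),
                                        d = numeric()))
  edges <- edges[order(edges$d, edges$i, edges$j), ]
  usedi <- logical(na); usedj <- logical(nb)
  keep <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    if (!usedi[edges$i[r]] && !usedj[edges$j[r]]) {
      keep[r] <- TRUE
      usedi[edges$i[r]] <- TRUE
      usedj[edges$j[r]] <- TRUE
    }
  }
  out <- edges[keep, ]
  rownames(out) <- NULL
  out
}

# canonicalise a find_foci result for comparison with o_find_foci
result_canonical <- function(res) {
  lab <- as.integer(res$labels)
  ids <- seq_len(nrow(res$peaks))
  lapply(ids, function(id) sort(which(lab == id)))
}

random_small_image <- function(nx, ny, levels = 4) {
  matrix(sample(0:(levels - 1), nx * ny, replace = TRUE), nx, ny)
}
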
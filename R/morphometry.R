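# Morphometry: centerline extraction and arclength-resolved diameter profiles.

# Zhang-Suen thinning, vectorized over the whole mask.
thinMask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dy, dx) p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      cur <- shift(pad, 0, 0)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- cur == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cur == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        cur[cond] <- 0L
        pad[2:(h + 1), 2:(w + 1)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)] > 0
}

# Skeleton pixels as an igraph with 8-neighbour edges weighted by metric
# length; returns list(graph, coords).
skeletonGraph <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0) return(NULL)
  h <- nrow(skel)
  yy <- ((idx - 1) %% h) + 1
  xx <- ((idx - 1) %/% h) + 1
  id <- match(idx, idx)
  key <- function(y, x) (x - 1) * h + y
  lookup <- stats::setNames(seq_along(idx), idx)
  edges <- NULL; wts <- NULL
  for (d in list(c(1, 0, 1), c(0, 1, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))) {
    ny <- yy + d[1]; nx <- xx + d[2]
    ok <- ny >= 1 & ny <= h & nx >= 1 & nx <= ncol(skel)
    nk <- key(ny[ok], nx[ok])
    j <- lookup[as.character(nk)]
    hit <- !is.na(j)
    if (any(hit)) {
      edges <- rbind(edges, cbind(which(ok)[hit], unname(j[hit])))
      wts <- c(wts, rep(d[3], sum(hit)))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wts)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  list(graph = g, x = xx, y = yy)
}

#' Extract the centerline of a tube-like lumen mask
#'
#' The mask is thinned to a skeleton (Zhang-Suen); the longest geodesic path
#' through the skeleton becomes the centerline, smoothed by a moving average
#' (window 5 px) for subpixel vertices; the endpoints are trimmed by 1.5 mean
#' lumen radius to avoid end-cap artifacts. If skeleton pixels remain farther
#' than a tolerance from the longest path (i.e. the skeleton genuinely
#' branches), a \code{branched-centerline} error is raised in single-vessel
#' mode.
#'
#' @param lumenMask logical matrix
#' @param config a \code{\linkS4class{PipelineConfig}}
#' @param branchTolerance px; skeleton side-branches longer than this trigger
#'   the branching error
#' @return data.frame with subpixel \code{x}, \code{y} and arclength \code{s}
#' @export
extractCenterline <- function(lumenMask, config = pipelineConfig(),
                              branchTolerance = 5) {
  skel <- thinMask(lumenMask)
  sg <- skeletonGraph(skel)
  if (is.null(sg) || igraph::vcount(sg$graph) < 3)
    abort("branched-centerline", "mask too small to carry a centerline")
  comp <- igraph::components(sg$graph)
  main <- which.max(comp$csize)
  inMain <- comp$membership == main
  # two-sweep diameter on the main component
  sub <- igraph::induced_subgraph(sg$graph, which(inMain))
  subIdx <- which(inMain)
  d1 <- igraph::distances(sub, v = 1)
  a <- which.max(d1)
  d2 <- igraph::distances(sub, v = a)
  b <- which.max(d2)
  pathV <- igraph::shortest_paths(sub, from = a, to = b)$vpath[[1]]
  path <- subIdx[as.integer(pathV)]
  dm <- EBImage::distmap(matrix(as.numeric(lumenMask), nrow(lumenMask)))
  meanR <- mean(dm[cbind(sg$y[path], sg$x[path])])
  # branch gate: any main-component skeleton pixel far from the path?
  # Thinning a wide tube leaves end forks up to ~1 radius long, so the
  # tolerance scales with the lumen radius, and forks where the vessel exits
  # the image (within ~1 radius of the border) are thinning artifacts, not
  # anatomy; genuine branches are longer and interior.
  offPath <- setdiff(which(inMain), path)
  if (length(offPath) > 0 && !config@multiVessel) {
    tol <- max(branchTolerance, 1.5 * meanR)
    margin <- meanR + 2
    h <- nrow(lumenMask); w <- ncol(lumenMask)
    interior <- sg$y[offPath] > margin & sg$y[offPath] <= h - margin &
      sg$x[offPath] > margin & sg$x[offPath] <= w - margin
    if (any(interior)) {
      dp <- igraph::distances(sg$graph, v = path, to = offPath[interior])
      if (any(apply(dp, 2, min) > tol))
        abort("branched-centerline",
              "skeleton branches beyond tolerance in single-vessel mode")
    }
  }
  x <- movingAverage(sg$x[path], 5L)
  y <- movingAverage(sg$y[path], 5L)
  # re-centre on the distance-map ridge: thinning cuts corners on curved
  # tubes, so each vertex is moved along its local normal to the subpixel
  # maximum of the (lightly smoothed) distance transform
  dm <- gaussBlur(dm, 1)
  np <- length(x)
  ip <- c(2:np, np); im <- c(1, 1:(np - 1))
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  tl <- pmax(sqrt(tx^2 + ty^2), 1e-9)
  nxv <- -ty / tl; nyv <- tx / tl
  tq <- seq(-max(3, 0.5 * meanR), max(3, 0.5 * meanR), by = 0.5)
  for (k in seq_len(np)) {
    vq <- bilinearSample(dm, y[k] + tq * nyv[k], x[k] + tq * nxv[k])
    vq[is.na(vq)] <- -Inf
    j <- which.max(vq)
    if (!is.finite(vq[j])) next
    tb <- tq[j]
    if (j > 1 && j < length(tq) && is.finite(vq[j - 1]) &&
        is.finite(vq[j + 1])) {
      den <- vq[j - 1] - 2 * vq[j] + vq[j + 1]
      if (den < -1e-9) tb <- tb + 0.5 * 0.5 * (vq[j - 1] - vq[j + 1]) / den
    }
    x[k] <- x[k] + tb * nxv[k]; y[k] <- y[k] + tb * nyv[k]
  }
  x <- movingAverage(x, 5L)
  y <- movingAverage(y, 5L)
  s <- arclength(x, y)
  # trim the end caps: the skeleton reaches them through diagonal thinning
  # forks up to sqrt(2) radii long, so 1.5 radii of arclength are removed
  trim <- 1.5 * meanR
  keep <- s >= trim & s <= max(s) - trim
  if (sum(keep) < 3)
    abort("branched-centerline", "centerline too short after end trimming")
  data.frame(x = x[keep], y = y[keep], s = s[keep] - min(s[keep]))
}

#' Wall-to-lumen ratio
#'
#' \code{WLR = 0.5 * (VD - LD) / LD}, dimensionless: half the combined wall
#' thickness relative to the lumen diameter.
#'
#' @param VD vessel (outer) diameter, um
#' @param LD lumen (inner) diameter, um
#' @return numeric vector of the same length
#' @export
wlr <- function(VD, LD) {
  if (any(LD <= 0, na.rm = TRUE))
    abort("invalid-lumen", "LD must be > 0")
  if (any(VD < LD, na.rm = TRUE))
    abort("inverted-wall", "VD must be >= LD")
  0.5 * (VD - LD) / LD
}

# Offsets (signed distances along the normal) of a polyline's intersections
# with the line through `ctr` along unit normal `nrm`; tangent `tng` is the
# perpendicular. Returns the crossing with the smallest |offset| and whether
# it lies on a valid (non-gap) stretch.
polylineCrossing <- function(poly, ctr, nrm, tng, maxOff) {
  if (nrow(poly) < 2) return(NULL)
  px <- poly$x - ctr[1]; py <- poly$y - ctr[2]
  ok <- !is.na(px)
  tproj <- px * tng[1] + py * tng[2]
  nproj <- px * nrm[1] + py * nrm[2]
  a <- tproj[-length(tproj)]; b <- tproj[-1]
  crossing <- which(!is.na(a) & !is.na(b) & a * b <= 0 & (a != b))
  if (length(crossing) == 0) return(NULL)
  lam <- -a[crossing] / (b[crossing] - a[crossing])
  off <- nproj[crossing] + lam * (nproj[crossing + 1] - nproj[crossing])
  keep <- abs(off) <= maxOff
  if (!any(keep)) return(NULL)
  crossing <- crossing[keep]; off <- off[keep]; lam <- lam[keep]
  j <- which.min(abs(off))
  valid <- TRUE
  if (!is.null(poly$valid))
    valid <- poly$valid[crossing[j]] && poly$valid[crossing[j] + 1]
  list(offset = off[j], valid = valid)
}

#' Arclength-resolved diameter profile
#'
#' At each arclength sample of the centerline a chord is cast perpendicular to
#' the local tangent (the only rotation-invariant choice). LD is the full
#' distance between its intersections with the two inner polylines, VD between
#' the two outer polylines, both converted to micrometres. Samples where an
#' outer intersection falls in a gap segment, or where a chord side is
#' missing, are flagged invalid.
#'
#' @param centerline data.frame from \code{\link{extractCenterline}}
#' @param seg a \code{\linkS4class{WallSegmentation}}
#' @param pixelScale micrometres per pixel
#' @param spacing arclength step between samples, px
#' @param smoothingWindow optional moving-average window applied to the VD and
#'   LD profiles (0 = none)
#' @return a \code{\linkS4class{MorphometryProfile}}
#' @export
diameterProfile <- function(centerline, seg, pixelScale = 1, spacing = 1,
                            smoothingWindow = 0L) {
  sq <- seq(0, max(centerline$s), by = spacing)
  ns <- length(sq)
  maxOff <- max(dim(seg@lumenMask))   # generous cap; chords are local anyway
  LD <- VD <- rep(NA_real_, ns)
  okOuter <- rep(FALSE, ns)
  eps <- min(1, spacing / 2)
  for (j in seq_len(ns)) {
    p0 <- interpPolyline(centerline, sq[j])
    pm <- interpPolyline(centerline, sq[j] - eps)
    pp <- interpPolyline(centerline, sq[j] + eps)
    tng <- c(pp$x - pm$x, pp$y - pm$y)
    tl <- sqrt(sum(tng^2))
    if (tl < 1e-9) next
    tng <- tng / tl
    nrm <- c(-tng[2], tng[1])
    ctr <- c(p0$x, p0$y)
    ci <- lapply(seg@inner, polylineCrossing, ctr = ctr, nrm = nrm,
                 tng = tng, maxOff = maxOff)
    co <- lapply(seg@outer, polylineCrossing, ctr = ctr, nrm = nrm,
                 tng = tng, maxOff = maxOff)
    if (!is.null(ci[[1]]) && !is.null(ci[[2]]) &&
        sign(ci[[1]]$offset) != sign(ci[[2]]$offset))
      LD[j] <- abs(ci[[1]]$offset - ci[[2]]$offset)
    if (!is.null(co[[1]]) && !is.null(co[[2]]) &&
        sign(co[[1]]$offset) != sign(co[[2]]$offset)) {
      VD[j] <- abs(co[[1]]$offset - co[[2]]$offset)
      okOuter[j] <- co[[1]]$valid && co[[2]]$valid
    }
  }
  if (mean(is.na(LD) & is.na(VD)) > 0.5)
    abort("profile-failed",
          "no perpendicular chord intersections for more than half the samples")
  if (smoothingWindow > 1) {
    LD <- movingAverage(LD, smoothingWindow)
    VD <- movingAverage(VD, smoothingWindow)
  }
  LDu <- LD * pixelScale; VDu <- VD * pixelScale
  valid <- okOuter & !is.na(LDu) & !is.na(VDu) & LDu > 0 & VDu >= LDu
  prof <- data.frame(position_um = sq * pixelScale, VD_um = VDu, LD_um = LDu,
                     wall_thickness_um = (VDu - LDu) / 2,
                     WLR = ifelse(!is.na(LDu) & LDu > 0,
                                  0.5 * (VDu - LDu) / LDu, NA_real_),
                     valid = valid)
  methods::new("MorphometryProfile", profile = prof, pixelScale = pixelScale)
}
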
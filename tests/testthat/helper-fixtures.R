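# shared fixture builders: all synthetic, generated at test time

pad_region <- function(m, p = 3L) {
  out <- matrix(0L, nrow(m) + 2L * p, ncol(m) + 2L * p)
  out[(p + 1):(p + nrow(m)), (p + 1):(p + ncol(m))] <- m
  out
}

digital_disk <- function(radius, value = 2L) {
  n <- 2L * radius + 10L
  cx <- (n + 1) / 2
  m <- matrix(0L, n, n)
  d2 <- outer((1:n - cx)^2, (1:n - cx)^2, "+")
  m[d2 <= radius^2] <- value
  m
}

digital_ball <- function(radius, value = 2L) {
  n <- 2L * radius + 5L
  cc <- (n + 1) / 2
  a <- array(0L, c(n, n, n))
  for (k in seq_len(n)) {
    d2 <- outer((1:n - cc)^2, (1:n - cc)^2, "+") + (k - cc)^2
    sl <- a[, , k]
    sl[d2 <= radius^2] <- value
    a[, , k] <- sl
  }
  a
}

# numeric arc length of r(theta) = R + A sin(k theta)
lobed_arc_length <- function(R, k, A, n = 20001L) {
  th <- seq(0, 2 * pi, length.out = n)
  r <- R + A * sin(k * th)
  dr <- A * k * cos(k * th)
  sum(sqrt(r^2 + dr^2)[-1] * diff(th))
}

# map a segmented region to the ground-truth id it mostly overlaps
dominant_gt_id <- function(seg, gt, id) {
  ov <- table(gt[seg == id])
  ov <- ov[!names(ov) %in% c("0", "1")]
  if (!length(ov)) NA_integer_ else as.integer(names(ov)[which.max(ov)])
}

# per-ground-truth-cell IoU against the best-overlapping segmented region
segmentation_iou <- function(seg, gt) {
  seg <- unclass(seg); gt <- unclass(gt)
  vapply(sort(unique(gt[gt >= 2L])), function(gid) {
    gm <- gt == gid
    ov <- table(seg[gm])
    ov <- ov[!names(ov) %in% c("0", "1")]
    if (!length(ov)) return(0)
    sid <- as.integer(names(ov)[which.max(ov)])
    sm <- seg == sid
    sum(gm & sm) / sum(gm | sm)
  }, numeric(1))
}

# fraction of ground-truth cells whose nucleus is correctly recovered by the
# pipeline (GT pairs cell id to the equal nucleus id by construction)
pairing_rate <- function(res, truth) {
  gcl <- unclass(truth$cells); gnl <- unclass(truth$nuclei)
  cl <- unclass(res$cells); nl <- unclass(res$nuclei)
  ids <- label_ids(truth$cells)
  good <- 0L
  for (gid in ids) {
    gm <- gcl == gid
    ov <- table(cl[gm]); ov <- ov[!names(ov) %in% c("0", "1")]
    if (!length(ov)) next
    ci <- as.integer(names(ov)[which.max(ov)])
    ni <- res$matches$nucleus_index[res$matches$cell_index == ci]
    if (!length(ni) || is.na(ni)) next
    gni <- dominant_gt_id(nl, gnl, ni)
    if (!is.na(gni) && gni == gid) good <- good + 1L
  }
  good / length(ids)
}

# label image of a 3-row brick pattern whose centre cell has exactly four
# neighbours (a guard-mother-cell configuration: two in-row sisters, one
# cell in each abutting row)
gmc_fixture <- function() {
  m <- matrix(0L, 30, 40)
  m[2:10, 2:39] <- 2L                       # top row cell (spans junctions)
  m[21:29, 2:39] <- 3L                      # bottom row cell
  m[12:19, 2:14] <- 4L                      # left sister (big)
  m[12:19, 16:22] <- 5L                     # small candidate (GMC)
  m[12:19, 24:39] <- 6L                     # right sister
  m[11, 2:39] <- 1L; m[20, 2:39] <- 1L      # row boundaries
  m[12:19, 15] <- 1L; m[12:19, 23] <- 1L    # in-row boundaries
  label_image(m, voxel_size = c(1, 1, 1))
}
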
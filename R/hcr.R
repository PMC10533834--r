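#' HCR-FISH image quantification
#'
#' Per-slice entropy-based binarization of 3-D intensity stacks (Renyi
#' entropy thresholds by default, with the Kapur maximum-entropy threshold as
#' a fallback on slices where the first pass produces a sudden spike in
#' binarized pixel counts), intensity-weighted signal masks, and
#' anatomical-region quantification with per-gene and per-region
#' normalizations.
#'
#' Thresholds operate on 256-bin histograms of min-max rescaled slices
#' (the reference algorithms are 8-bit). A threshold t assigns bins 0..t to
#' background and bins t+1..255 to foreground.
#'
#' @name hcr_quant
NULL

# shared machinery: per-threshold two-class entropy sums over a 256-bin
# histogram; returns the objective for every candidate t (0-based), NA where
# a class is empty
.entropy_objective <- function(histogram, alpha) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  if (sum(histogram > 0) < 2) stop("degenerate histogram")
  p <- histogram / sum(histogram)
  P0 <- cumsum(p)
  P1 <- 1 - P0
  valid <- P0 > 0 & P1 > 0
  obj <- rep(NA_real_, 256)
  if (alpha == 1) {
    plogp <- ifelse(p > 0, p * log(p), 0)
    S0 <- cumsum(plogp)
    S1 <- sum(plogp) - S0
    obj[valid] <- (log(P0) - S0 / P0 + log(P1) - S1 / P1)[valid]
  } else {
    pa <- p^alpha
    C0 <- cumsum(pa)
    C1 <- sum(pa) - C0
    obj[valid] <- (log(C0 / P0^alpha) + log(C1 / P1^alpha))[valid] /
      (1 - alpha)
  }
  obj
}

#' Kapur maximum-entropy threshold
#'
#' Returns the 0-based bin t maximizing the summed Shannon entropies of the
#' two classes split at t; ties go to the lowest t and empty classes are
#' excluded from the argmax domain.
#'
#' @param histogram 256-bin count vector.
#' @return integer threshold in 0..255.
#' @export
kapur_max_entropy_threshold <- function(histogram) {
  obj <- .entropy_objective(histogram, alpha = 1)
  which.max(obj) - 1L
}

#' Renyi-entropy threshold
#'
#' Per alpha, the threshold maximizing the two-class Renyi entropy sum
#' (alpha = 1 reduces to the Kapur objective). With the default three alphas
#' the per-alpha thresholds are sorted and combined by the Sahoo et al.
#' (1997) weighting rule, as in the standard auto-threshold reference
#' implementation.
#'
#' @param histogram 256-bin count vector.
#' @param alphas Renyi orders (default 0.5, 1, 2).
#' @return list with `threshold` (combined, integer 0..255) and `per_alpha`
#'   (named per-alpha thresholds).
#' @export
renyi_entropy_threshold <- function(histogram, alphas = c(0.5, 1, 2)) {
  ts <- vapply(alphas, function(a)
    which.max(.entropy_objective(histogram, a)) - 1L, integer(1))
  names(ts) <- paste0("alpha", alphas)
  if (length(ts) == 1) return(list(threshold = ts[[1]], per_alpha = ts))
  if (length(ts) != 3)
    stop("the combination rule is defined for exactly 3 alphas")
  p <- histogram / sum(histogram)
  P1 <- cumsum(p)
  P2 <- 1 - P1
  st <- sort(ts)
  t1 <- st[1]; t2 <- st[2]; t3 <- st[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) beta <- c(1, 2, 1) else beta <- c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) beta <- c(3, 1, 0) else beta <- c(1, 2, 1)
  }
  omega <- P1[t3 + 1] - P1[t1 + 1]
  t_final <- t1 * (P1[t1 + 1] + 0.25 * omega * beta[1]) +
    0.25 * t2 * omega * beta[2] +
    t3 * (P2[t3 + 1] + 0.25 * omega * beta[3])
  list(threshold = as.integer(t_final), per_alpha = ts)
}

#' Flag spike slices from per-slice binarized pixel counts
#'
#' A slice is flagged when its count exceeds `spike_factor` times the median
#' count of its up-to-`window` neighboring slices on each side (self
#' excluded; boundary slices use the available neighbors).
#'
#' @param counts per-slice binarized pixel counts (>= 5 slices).
#' @param spike_factor multiplicative spike criterion.
#' @param window neighbor half-width.
#' @return integer vector of flagged z indices (1-based).
#' @export
spike_slices <- function(counts, spike_factor = 3, window = 2) {
  nz <- length(counts)
  if (nz < 5) stop("need at least 5 slices for spike detection")
  flagged <- integer(0)
  for (z in seq_len(nz)) {
    nb <- setdiff(max(1, z - window):min(nz, z + window), z)
    if (counts[z] > spike_factor * stats::median(counts[nb]))
      flagged <- c(flagged, z)
  }
  flagged
}

#' Binarize a 3-D stack slice by slice
#'
#' Pass 1 thresholds every slice with the Renyi-entropy rule on the slice's
#' own 256-bin histogram (after min-max rescaling to 0..255); pass 2 flags
#' slices whose binarized pixel count spikes relative to neighboring slices
#' and re-thresholds them with the Kapur maximum-entropy rule. Pixels
#' strictly above the threshold are signal. The signal stack is the mask
#' multiplied by the original intensities.
#'
#' @param stack 3-D array `(z, y, x)` of non-negative intensities.
#' @param spike_factor,spike_window see [spike_slices()].
#' @param alphas Renyi orders for pass 1.
#' @return a `binarization` list: `mask` (logical array), `signal`
#'   (mask * intensity), per-slice `threshold` and `method`
#'   ("renyi", "maxentropy" or "degenerate"), `spike_slices`.
#' @export
binarize_stack <- function(stack, spike_factor = 3, spike_window = 2,
                           alphas = c(0.5, 1, 2)) {
  stopifnot(length(dim(stack)) == 3)
  nz <- dim(stack)[1]
  mask <- array(FALSE, dim(stack))
  threshold <- rep(NA_integer_, nz)
  method <- rep(NA_character_, nz)
  scaled <- vector("list", nz)
  for (z in seq_len(nz)) {
    m <- stack[z, , ]
    rng <- range(m)
    if (rng[1] == rng[2] ||
        sum(tabulate(round((m - rng[1]) / (rng[2] - rng[1]) * 255) + 1,
                     256) > 0) < 2) {
      warning("slice ", z, " has a degenerate histogram; mask left empty")
      method[z] <- "degenerate"
      next
    }
    s <- round((m - rng[1]) / (rng[2] - rng[1]) * 255)
    scaled[[z]] <- s
    threshold[z] <- renyi_entropy_threshold(
      tabulate(s + 1, 256), alphas = alphas)$threshold
    method[z] <- "renyi"
    mask[z, , ] <- s > threshold[z]
  }
  spikes <- integer(0)
  if (nz >= 5) {
    counts <- apply(mask, 1, sum)
    spikes <- spike_slices(counts, spike_factor = spike_factor,
                           window = spike_window)
    for (z in spikes) {
      if (method[z] == "degenerate") next
      threshold[z] <- kapur_max_entropy_threshold(
        tabulate(scaled[[z]] + 1, 256))
      method[z] <- "maxentropy"
      mask[z, , ] <- scaled[[z]] > threshold[z]
    }
  }
  structure(list(mask = mask, signal = mask * stack, threshold = threshold,
                 method = method, spike_slices = spikes),
            class = "binarization")
}

#' Quantify binarized signal within anatomical regions
#'
#' Per region: the sum of intensities over binarized voxels inside the region
#' (signal_sum) and the mean intensity of in-region non-binarized voxels
#' (background_mean).
#'
#' @param stack 3-D intensity array.
#' @param binarization a `binarization` from [binarize_stack()] (or a logical
#'   mask array).
#' @param region_masks named list of logical arrays, same shape as `stack`.
#' @return data.frame per region: signal_sum, background_mean, n_signal,
#'   n_background, background_undefined.
#' @export
quantify_regions <- function(stack, binarization, region_masks) {
  mask <- if (inherits(binarization, "binarization")) binarization$mask
  else binarization
  stopifnot(identical(dim(mask), dim(stack)),
            length(region_masks) >= 1, !is.null(names(region_masks)))
  rows <- lapply(names(region_masks), function(rn) {
    rm <- region_masks[[rn]]
    stopifnot(identical(dim(rm), dim(stack)))
    sig <- rm & mask
    bg <- rm & !mask
    data.frame(region = rn,
               signal_sum = sum(stack[sig]),
               background_mean = if (any(bg)) mean(stack[bg]) else NA_real_,
               n_signal = sum(sig), n_background = sum(bg),
               background_undefined = !any(bg))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Build the region x gene signal table with normalizations
#'
#' Replicate quantifications of the same gene are averaged. gene_normalized
#' divides each gene's (averaged) signal sums by that gene's maximum across
#' regions; region_normalized divides background-normalized values
#' (signal_sum / background_mean) by each region's maximum across genes.
#'
#' @param quants named list: gene -> list of per-replicate data.frames from
#'   [quantify_regions()].
#' @return a `signal_table` list: `signal_sum`, `background_mean`,
#'   `gene_normalized`, `region_normalized` (genes x regions matrices) and
#'   `long` (tidy data.frame).
#' @export
signal_table <- function(quants) {
  stopifnot(length(quants) >= 1, !is.null(names(quants)))
  genes <- names(quants)
  regions <- quants[[1]][[1]]$region
  avg <- function(g, col) {
    reps <- vapply(quants[[g]], function(q) {
      stopifnot(identical(q$region, regions))
      q[[col]]
    }, numeric(length(regions)))
    rowMeans(as.matrix(reps))
  }
  ss <- t(vapply(genes, avg, numeric(length(regions)), col = "signal_sum"))
  bg <- t(vapply(genes, avg, numeric(length(regions)),
                 col = "background_mean"))
  colnames(ss) <- colnames(bg) <- regions
  gene_norm <- ss / apply(ss, 1, max)
  bg_norm <- ss / bg
  region_norm <- sweep(bg_norm, 2, apply(bg_norm, 2, max), "/")
  long <- data.frame(gene = rep(genes, each = length(regions)),
                     region = rep(regions, length(genes)),
                     signal_sum = as.vector(t(ss)),
                     background_mean = as.vector(t(bg)),
                     gene_normalized = as.vector(t(gene_norm)),
                     region_normalized = as.vector(t(region_norm)))
  structure(list(signal_sum = ss, background_mean = bg,
                 gene_normalized = gene_norm,
                 region_normalized = region_norm, long = long),
            class = "signal_table")
}

#' Binarize and quantify stacks for several genes
#'
#' Convenience wrapper: binarizes each replicate stack, quantifies it within
#' the region masks and assembles the [signal_table()].
#'
#' @param stacks_by_gene named list: gene -> list of 3-D intensity arrays
#'   (replicates).
#' @param region_masks named list of logical arrays.
#' @param ... passed to [binarize_stack()].
#' @return a `signal_table`.
#' @export
region_signal <- function(stacks_by_gene, region_masks, ...) {
  quants <- lapply(stacks_by_gene, function(reps)
    lapply(reps, function(st)
      quantify_regions(st, binarize_stack(st, ...), region_masks)))
  signal_table(quants)
}
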
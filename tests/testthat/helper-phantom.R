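# small phantoms for fast unit tests; acceptance tests use larger grids
smallConfig <- function(timepoint = "baseline", cohort = "infarct",
                        seed = 1L, ...) {
  defaultPhantomConfig(timepoint, cohort, seed = seed,
                       gridSize = c(48L, 48L), nSlices = 4L,
                       infarctSlices = if (cohort == "infarct") 2:3
                       else integer(), ...)
}

# single-voxel MOLLI series from raw magnitudes (for fitter edge cases)
molliSeries1 <- function(y, TI) {
  new("ImageSeries", data = array(y, c(1, 1, 1, length(TI))),
      meta = data.frame(TI = TI), pixelSpacing = NA_real_, sliceZ = 0,
      kind = "molli")
}

# series from an arbitrary signal array stack
seriesFromStack <- function(stack, meta, kind) {
  new("ImageSeries", data = stack, meta = meta, pixelSpacing = NA_real_,
      sliceZ = numeric(dim(stack)[3]), kind = kind)
}

# the default 12-direction high-b set
.fibDirs12 <- function() cmrphantom:::.fibDirections(12L)

# random rotation matrix (uniform via QR of Gaussian matrix)
randomRotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  Q %*% diag(sign(diag(qr.R(qrd))))
}
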
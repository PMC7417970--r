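# shared fixture builders; everything is generated in code at test time

small_world <- local({
  memo <- new.env(parent = emptyenv())
  function(dims = c(20, 24, 20), seed = 7L, ...) {
    key <- paste(c(dims, seed, ...), collapse = "_")
    if (is.null(memo[[key]])) {
      spec <- phantom_spec(grid_dims = dims, seed = seed, ...)
      memo[[key]] <- list(spec = spec, template = build_template(spec))
    }
    memo[[key]]
  }
})

# two-tissue spherical phantom: WM core, GM shell, known activities
sphere_phantom <- function(dims = c(30, 30, 30), voxel_mm = 3,
                           g = 4, w = 1, r_wm = 6, r_gm = 11) {
  a <- array(0, dims)
  ctr <- (dims + 1) / 2
  r <- sqrt((slice.index(a, 1) - ctr[1])^2 +
              (slice.index(a, 2) - ctr[2])^2 +
              (slice.index(a, 3) - ctr[3])^2)
  gm <- (r > r_wm & r <= r_gm) * 1
  wm <- (r <= r_wm) * 1
  list(
    gm = new_volume(gm, voxel_mm),
    wm = new_volume(wm, voxel_mm),
    truth = new_volume(g * gm + w * wm, voxel_mm),
    r = r, g = g, w = w
  )
}

# direct (non-phantom) stack of linear-in-age images with iid noise
linear_age_images <- function(n, dims, intercept, slope, sd, ages = NULL,
                              voxel_mm = 3) {
  if (is.null(ages)) ages <- stats::runif(n, 30, 65)
  imgs <- lapply(seq_len(n), function(i) {
    new_volume(array(intercept + slope * ages[i] +
                       stats::rnorm(prod(dims), 0, sd), dims), voxel_mm)
  })
  list(images = imgs, ages = ages)
}
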
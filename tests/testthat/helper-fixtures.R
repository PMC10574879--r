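# fixtures built in code: arcs, bumps, images

arc_points <- function(radius, span = 2 * pi / 3, n = 60) {
  th <- seq(-span / 2, span / 2, length.out = n)
  cbind(radius * sin(th), radius * cos(th))
}

# write a calibrated image to a PNG the extraction front end can read
write_test_png <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(img$pixels) / 255), path)
  path
}
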
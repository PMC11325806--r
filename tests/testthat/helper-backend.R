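# Crop a global-coordinate instance mask to a tile window (tile-local
# coordinates), dropping it if no foreground falls inside -- a stand-in for
# any tile-wise segmentation backend operating on ground truth.
crop_to_tile <- function(mask, win) {
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  r0 <- max(mask$offset[1], win$row0); r1 <- min(mask$offset[1] + nr - 1L,
                                                 win$row0 + win$rows - 1L)
  c0 <- max(mask$offset[2], win$col0); c1 <- min(mask$offset[2] + nc - 1L,
                                                 win$col0 + win$cols - 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  sub <- mask$grid[(r0 - mask$offset[1] + 1L):(r1 - mask$offset[1] + 1L),
                   (c0 - mask$offset[2] + 1L):(c1 - mask$offset[2] + 1L),
                   drop = FALSE]
  if (sum(sub) == 0L) return(NULL)
  woodmorph:::tighten_mask(
    instance_mask(sub, offset = c(r0 - win$row0, c0 - win$col0),
                  class_label = mask$class_label,
                  confidence = mask$confidence,
                  instance_id = mask$instance_id))
}
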
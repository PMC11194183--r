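# Shared fixture builders (all fixtures constructed in code).

# Disc of the given intensity on a white (255) background; returns the
# image plus the logical pixel set of the disc.
make_disc_image <- function(size = 40, radius = 12, intensity = 100,
                            centre = c(size / 2, size / 2)) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  disc <- (rows - centre[1])^2 + (cols - centre[2])^2 <= radius^2
  px <- matrix(255, size, size)
  px[disc] <- intensity
  list(image = shell_image(px), disc = disc)
}

as_mask <- function(logical_matrix) {
  structure(logical_matrix, excluded_regions = list(),
            class = c("shell_mask", "matrix", "array"))
}

# The 15-row mean seasonal chemistry table used across tests.
chem <- seasonal_chemistry()
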
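# minimal donor/hydrogen/acceptor fixture with a geometry dial

# topology of one donor/hydrogen/acceptor triplet plus padding atoms
hb_toy <- function() {
  atoms <- data.frame(
    name = c("NE2", "HE2", "CA", "OE1", "CA"),
    element = c("N", "H", "C", "O", "C"),
    resno = c(1, 1, 1, 2, 2),
    resname = c("HIS", "HIS", "HIS", "GLU", "GLU"),
    chain = "A", stringsAsFactors = FALSE)
  topology(atoms)
}

# frame with prescribed donor-acceptor distance and D-H...A angle
hb_frame <- function(d, angle_deg) {
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  ang <- angle_deg * pi / 180
  u <- c(-1, 0, 0)                      # H -> D direction
  v <- c(-cos(ang), sin(ang), 0)        # direction making `ang` with u
  # place A along v from H so that |D - A| = d
  f <- function(t) sqrt(sum((H + t * v - D)^2)) - d
  t <- uniroot(f, c(1e-6, d + 2))$root
  A <- H + t * v
  rbind(D, H, c(5, 5, 5), A, c(6, 6, 6))
}

hb_spec <- function() {
  interaction_spec("hbond", "toy",
                   a = list(resno = 1, name = "NE2"),
                   h = list(resno = 1, name = "HE2"),
                   b = list(resno = 2, name = "OE1"))
}
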
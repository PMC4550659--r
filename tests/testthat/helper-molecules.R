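# Shared in-code fixtures: the two printed charge-dialect documents a legacy
# corpus mixes, plus small geometries built from known parameters.

legacy_dialect_cml <- paste0(
  '<molecule id="NSC138467" name="NSC138467">',
  '<identifier version="0.932Beta" tautomeric="0">',
  '<basic>C13H21N2O,1H3-12H(2H3)15(13H(3H3)4H3)11(16)10-7H-6H-8H-14(5H3)9H-10</basic>',
  '<charge>+1</charge>',
  '</identifier>',
  '<atomArray><atom id="a1" elementType="C"/></atomArray>',
  '</molecule>')

attr_dialect_cml <- paste0(
  '<molecule id="NSC138467" formalCharge="1" name="mol1">',
  '<atomArray><atom id="a1" elementType="C"/></atomArray>',
  '</molecule>')

# water with O-H 0.96 A and H-O-H 104.5 deg, built from those parameters
water_atoms <- function(r = 0.96, theta = 104.5) {
  th <- theta * pi / 180
  atoms(c("O", "H", "H"),
        x = c(0, r, r * cos(th)),
        y = c(0, 0, r * sin(th)),
        z = c(0, 0, 0))
}

h2_atoms <- function(d = 0.74) {
  atoms(c("H", "H"), x = c(0, d), y = 0, z = 0)
}

random_atoms <- function(n, elements = c("C", "N", "O", "H"), span = 4,
                         min_sep = 0.5) {
  repeat {
    at <- atoms(sample(elements, n, replace = TRUE),
                stats::runif(n, -span, span), stats::runif(n, -span, span),
                stats::runif(n, -span, span))
    d <- stats::dist(as.matrix(at[, c("x", "y", "z")]))
    if (n < 2 || min(d) > min_sep) return(at)
  }
}

dist_matrix <- function(at) {
  as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
}

rigid_motion <- function(at, angle = 0.7, axis = c(1, 2), shift = c(5, -3, 2)) {
  m <- as.matrix(at[, c("x", "y", "z")])
  r <- diag(3)
  r[axis[1], axis[1]] <- cos(angle); r[axis[2], axis[2]] <- cos(angle)
  r[axis[1], axis[2]] <- -sin(angle); r[axis[2], axis[1]] <- sin(angle)
  m <- m %*% r
  out <- at
  out$x <- m[, 1] + shift[1]; out$y <- m[, 2] + shift[2]
  out$z <- m[, 3] + shift[3]
  out
}
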
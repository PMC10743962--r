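# Shared fixtures, built once per test run. Phantoms are generated in code;
# nothing is read from disk.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtureCache[[name]]))
    assign(name, build(), envir = .fixtureCache)
  .fixtureCache[[name]]
}

straightPhantom <- function() fixture("straight", function()
  generatePhantom(phantomSpec(centerlineModel = "straight", targetCobb = 0,
                              seed = 11)))

curvedPhantom <- function() fixture("curved", function()
  generatePhantom(phantomSpec(targetCobb = 25, seed = 3)))

# Independent rasterizer for a rotated rectangle (oracle for box geometry;
# deliberately not sharing code with the package).
rasterRotRect <- function(nr, nc, r0, c0, halfW, halfH, thetaDeg) {
  th <- thetaDeg * pi / 180
  m <- matrix(0L, nr, nc)
  for (r in 1:nr) for (cc in 1:nc) {
    u <- (cc - c0) * cos(th) + (r - r0) * sin(th)
    v <- -(cc - c0) * sin(th) + (r - r0) * cos(th)
    if (abs(u) <= halfW && abs(v) <= halfH) m[r, cc] <- 1L
  }
  m
}

# Direction-vector oracle for the angle between two endplate lines with
# slopes zi, zj: angle between (1, zi) and (1, zj) via the normalized dot
# product, folded to [0, 90].
slopeAngleOracle <- function(zi, zj) {
  v1 <- c(1, zi) / sqrt(1 + zi^2)
  v2 <- c(1, zj) / sqrt(1 + zj^2)
  a <- acos(pmin(1, pmax(-1, sum(v1 * v2)))) * 180 / pi
  min(a, 180 - a)
}
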
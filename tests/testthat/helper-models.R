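# Shared fixtures: all built in code, no files.

right_triangle <- function() rbind(c(0, 0), c(100, 0), c(0, 100))

# Random interior point of a triangle via uniform barycentric sampling.
random_interior_point <- function(triangle) {
  w <- -log(stats::runif(3))
  w <- w / sum(w)
  as.numeric(t(triangle) %*% w)
}

# Small random rigid-body model whose segment-CoM circle stays well inside
# the default support triangle.
random_model <- function() {
  rigid_body_model(
    segment = rigid_segment(stats::runif(1, 1, 5), stats::runif(2, -8, 8)),
    rest_mass_kg = stats::runif(1, 20, 60),
    rest_com_cm = stats::runif(2, 0, 15),
    carrier_mass_kg = stats::runif(1, 5, 15),
    carrier_com_cm = stats::runif(2, 0, 15)
  )
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
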
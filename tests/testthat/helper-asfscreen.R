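# Shared helpers: independent oracles and small constructed inputs.

# Independent brute-force k-subset generator (recursive include/exclude),
# deliberately not using utils::combn, so enumeration counts can be checked
# against an implementation-independent oracle.
brute_subsets <- function(labels, k) {
  if (k == 0) return(list(character()))
  if (length(labels) < k) return(list())
  head_label <- labels[1]
  rest <- labels[-1]
  with_head <- lapply(brute_subsets(rest, k - 1),
                      function(s) c(head_label, s))
  c(with_head, brute_subsets(rest, k))
}

# Closed-form ordinary least squares via the normal equations.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Donor tibble for a perfect octahedron of radius r around the origin.
octahedral_donors <- function(r = 2.1) {
  tibble::tibble(
    atom_index = 0:5,
    element = c("O", "O", "O", "O", "O", "N"),
    label = c(paste0("O", 1:5), "N1"),
    x = c(r, -r, 0, 0, 0, 0),
    y = c(0, 0, r, -r, 0, 0),
    z = c(0, 0, 0, 0, r, -r)
  )
}

# Minimal descriptor tibble built in code (one row per distance set).
make_descriptors <- function(distances, dipole = 10, energy = 1e6,
                             volume = 650, area = 660, charge = 1) {
  rows <- lapply(seq_along(distances), function(i) {
    d <- distances[[i]]
    row <- tibble::tibble(
      complex_id = sprintf("cx-%02d", i),
      donors = paste(paste0("O", seq_along(d)), collapse = ";"),
      dipole_debye = dipole[min(i, length(dipole))]
    )
    for (j in 1:6) row[[paste0("d", j)]] <- if (j <= length(d)) d[j] else NA_real_
    row$area_A2 <- area
    row$volume_A3 <- volume
    row$molar_mass <- 650
    row$energy_J <- energy[min(i, length(energy))]
    row$charge <- charge
    row$incomplete <- length(d) < 6
    row$has_aqua <- FALSE
    row
  })
  dplyr::bind_rows(rows)
}

# A tiny water SDF written to a temp file.
write_water_sdf <- function() {
  path <- withr::local_tempfile(fileext = ".sdf",
                                .local_envir = parent.frame())
  writeLines(c(
    "water",
    "  test",
    "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.7572    0.5865    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.7572    0.5865    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "M  END",
    "$$$$"
  ), path)
  path
}
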
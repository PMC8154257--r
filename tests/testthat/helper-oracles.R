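# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, brute-force enumeration, and
# base-R reference implementations.

# closed-form normal equations for simple OLS; returns c(intercept, slope)
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# brute-force O(n^2) single-linkage friends-of-friends labelling: full
# pairwise distance matrix, then union-find over qualifying pairs
oracle_fof <- function(xyz, thr) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    pairs <- which(upper.tri(d) & d <= thr + 1e-9, arr.ind = TRUE)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# are two cluster labellings the same partition of the same points?
expect_same_partition <- function(lab1, lab2) {
  expect_equal(length(lab1), length(lab2))
  expect_equal(length(unique(lab1)), length(unique(lab2)))
  agree <- all(vapply(split(lab2, lab1),
                      function(v) length(unique(v)) == 1L, logical(1)))
  expect_true(agree)
}

# exhaustive minimum over within-element atom permutations; element
# classes are independent, so per-class minima add up
oracle_sym_rmsd <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  xa <- cbind(a$x, a$y, a$z)
  xb <- cbind(b$x, b$y, b$z)
  total <- 0
  for (el in unique(a$element)) {
    ia <- which(a$element == el)
    ib <- which(b$element == el)
    stopifnot(length(ia) == length(ib))
    best <- Inf
    for (p in perms(ib)) {
      cost <- sum((xa[ia, , drop = FALSE] - xb[p, , drop = FALSE])^2)
      if (cost < best) best <- cost
    }
    total <- total + best
  }
  sqrt(total / nrow(a))
}

# minimal fixed-column PDB coordinate parser, independent of bio3d
oracle_pdb_coords <- function(path) {
  lines <- readLines(path)
  rec <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  data.frame(
    name = trimws(substr(rec, 13, 16)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)))
}

# write PDB-format text lines to a temp file, return the path
write_pdb_text <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  path
}

pdb_line <- function(record = "HETATM", serial = 1, name = "C1",
                     resname = "LIG", chain = "A", resno = 1,
                     x = 0, y = 0, z = 0, occ = 1, b = 0, element = "C",
                     alt = " ") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ, b,
          element)
}
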
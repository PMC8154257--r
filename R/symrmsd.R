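## Symmetry-corrected RMSD between two poses of the same molecule.
##
## Chemically equivalent atoms (same element) are allowed to exchange:
## within each element class the atom correspondence minimising the total
## squared distance is found by the Hungarian algorithm, so e.g. a 180
## degree flip of a carboxylate no longer inflates the RMSD. No
## superposition is applied -- docked and reference poses are compared in
## the common receptor frame.

#' Symmetry-corrected RMSD between two poses
#'
#' @param a,b [molecule_pose()] objects of the same molecule in a common
#'   frame. After exclusions they must contain the same multiset of
#'   elements.
#' @param variant `"hungarian"` (default) finds, per element class, the
#'   minimum-cost atom assignment; `"naive"` pairs atoms in input order.
#' @param exclude Integer serial numbers to leave out (e.g. a flexible
#'   substituent protruding out of the binding pocket); applied to both
#'   poses.
#' @param include_hydrogens Include H/D atoms (default `FALSE`: ligand
#'   hydrogen positions in PDB files are usually unreliable).
#' @return An object of class `rmsd_result`: list with `rmsd` (A),
#'   `mapping` (data frame `serial_a`, `serial_b`, `element`, `dist`),
#'   `variant`, `excluded`, `n_atoms`.
#' @export
symmetry_rmsd <- function(a, b, variant = c("hungarian", "naive"),
                          exclude = integer(0), include_hydrogens = FALSE) {
  variant <- match.arg(variant)
  fa <- .rmsd_atoms(a, exclude, include_hydrogens)
  fb <- .rmsd_atoms(b, exclude, include_hydrogens)
  ta <- table(fa$element); tb <- table(fb$element)
  if (length(ta) != length(tb) || !identical(sort(names(ta)), sort(names(tb))) ||
      !all(ta == tb[names(ta)])) {
    .stopf("element multisets differ: [%s] vs [%s]",
           paste(sprintf("%s:%d", names(ta), ta), collapse = " "),
           paste(sprintf("%s:%d", names(tb), tb), collapse = " "))
  }
  xa <- pose_xyz(fa); xb <- pose_xyz(fb)
  if (variant == "naive") {
    ia <- seq_len(nrow(fa)); ib <- seq_len(nrow(fb))
  } else {
    ia <- integer(0); ib <- integer(0)
    for (el in sort(names(ta))) {
      ra <- which(fa$element == el); rb <- which(fb$element == el)
      cost <- outer(rowSums(xa[ra, , drop = FALSE]^2),
                    rowSums(xb[rb, , drop = FALSE]^2), "+") -
        2 * xa[ra, , drop = FALSE] %*% t(xb[rb, , drop = FALSE])
      assign <- .solve_assignment(cost)
      ia <- c(ia, ra); ib <- c(ib, rb[assign])
    }
  }
  d2 <- rowSums((xa[ia, , drop = FALSE] - xb[ib, , drop = FALSE])^2)
  d2 <- pmax(d2, 0)
  structure(
    list(rmsd = sqrt(mean(d2)),
         mapping = data.frame(serial_a = fa$serial[ia],
                              serial_b = fb$serial[ib],
                              element = fa$element[ia], dist = sqrt(d2)),
         variant = variant, excluded = as.integer(exclude),
         n_atoms = length(ia)),
    class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("rmsd_result (%s): %.4f A over %d atoms%s\n", x$variant,
              x$rmsd, x$n_atoms,
              if (length(x$excluded))
                sprintf(", %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

.rmsd_atoms <- function(pose, exclude, include_hydrogens) {
  keep <- !(pose$serial %in% exclude)
  if (!include_hydrogens) keep <- keep & !(pose$element %in% c("H", "D"))
  if (!any(keep)) .stopf("no atoms left in pose '%s'", pose_label(pose))
  out <- pose[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Minimum-cost perfect assignment on a square cost matrix
## (Jonker-Volgenant style shortest augmenting paths, O(n^3)).
## Returns the column assigned to each row. Element classes in ligands
## are small, so a plain R implementation is adequate.
.solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 1L) return(1L)
  J <- n + 1L                        # virtual start column
  u <- numeric(n); v <- numeric(J)
  p <- integer(J)                    # p[j]: row assigned to column j
  way <- integer(J)
  for (i in seq_len(n)) {
    p[J] <- i
    j0 <- J
    minv <- rep(Inf, n)
    used <- logical(J)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(J)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assign[p[j]] <- j
  assign
}
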
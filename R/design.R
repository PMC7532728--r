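#' Build a density-gradient pot experiment design
#'
#' Constructs the full factorial design of a two-species pairwise
#' competition experiment: for each focal species and watering treatment,
#' a set of no-neighbour pots plus pots with conspecific or heterospecific
#' neighbours thinned to fixed densities. The default replicate scheme is
#' 16 pots at density 0 and 12/8/8 pots for each neighbour type at
#' densities 4/10/20 — more replication at low density, where variation in
#' low-density growth is largest — giving 72 pots per focal species and
#' treatment (288 in total).
#'
#' @param reps Named integer vector of replicate counts per neighbour
#'   density; names are the densities. The density-0 entry is a single
#'   shared no-neighbour cell; every other density gets one conspecific
#'   and one heterospecific cell at that count.
#' @param treatments Character vector of treatment labels.
#' @param species Character vector of length 2: labels for focal species
#'   `i` and `j`.
#' @return A data.frame of class `"pot_design"` with columns `focal`,
#'   `treatment`, `neighbour` (`"none"`, `"conspecific"`,
#'   `"heterospecific"`), `density` and `reps`.
#' @examples
#' d <- make_design()
#' sum(d$reps)  # 288 pots
#' @export
make_design <- function(reps = c(`0` = 16, `4` = 12, `10` = 8, `20` = 8),
                        treatments = c("dry", "wet"),
                        species = c("i", "j")) {
  if (is.null(names(reps)) || anyNA(suppressWarnings(as.numeric(names(reps)))))
    stop("reps must be named by neighbour density")
  dens <- as.numeric(names(reps))
  if (any(dens < 0) || any(dens != round(dens)))
    stop("neighbour densities must be non-negative integers")
  if (any(!is.finite(reps)) || any(reps <= 0) || any(reps != round(reps)))
    stop("replicate counts must be positive integers")
  if (length(species) != 2L || anyDuplicated(species))
    stop("species must be two distinct labels")
  if (!any(dens == 0))
    stop("design must include a density-0 (no neighbour) cell")

  cell <- function(d, r) {
    if (d == 0)
      data.frame(neighbour = "none", density = 0, reps = r)
    else
      data.frame(neighbour = c("conspecific", "heterospecific"),
                 density = d, reps = r)
  }
  cells <- do.call(rbind, Map(cell, dens, as.integer(reps)))
  grid <- expand.grid(focal = species, treatment = treatments,
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    cbind(grid[rep(k, nrow(cells)), , drop = FALSE], cells,
          row.names = NULL)
  }))
  rownames(out) <- NULL
  class(out) <- c("pot_design", "data.frame")
  out
}

#' @export
print.pot_design <- function(x, ...) {
  cat(sprintf("Pot experiment design: %d cells, %d pots total\n",
              nrow(x), sum(x$reps)))
  per <- stats::aggregate(reps ~ focal + treatment, data = x, sum)
  print.data.frame(per, row.names = FALSE)
  invisible(x)
}
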
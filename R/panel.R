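#' Longitudinal panel representation
#'
#' A panel is a long-format data frame with one row per person-visit and
#' columns:
#' \describe{
#'   \item{id}{integer person identifier}
#'   \item{t}{visit index, `0:(T-1)` consecutive within person (T = 5)}
#'   \item{b_bin, b_cont}{time-constant baseline confounders (binary and
#'     continuous), constant within person}
#'   \item{x}{continuous time-varying confounder (NA when unobserved)}
#'   \item{a}{binary treatment, never missing; structurally 0 at t = 0}
#'   \item{y}{continuous outcome (NA when unobserved)}
#'   \item{r_x, r_y}{observation indicators: 1 when the cell is observed}
#'   \item{c}{monotone drop-out indicator, absorbing once 1}
#' }
#'
#' @param panel data frame to validate
#' @param complete require all cells observed
#' @return the validated panel (invisibly for `validate_panel`)
#' @export
validate_panel <- function(panel, complete = FALSE) {
  need <- c("id", "t", "b_bin", "b_cont", "x", "a", "y", "r_x", "r_y", "c")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (any(is.na(panel$a))) stop("treatment column 'a' must be fully observed")
  tt <- tapply(panel$t, panel$id, function(v) identical(sort(v), seq(0L, length(v) - 1L)))
  if (!all(unlist(tt))) stop("each id must have consecutive visits starting at 0")
  nt <- table(tapply(panel$t, panel$id, length))
  if (length(nt) != 1L) stop("all ids must have the same number of visits")
  if (any((panel$r_x == 0) != is.na(panel$x))) stop("r_x = 0 must coincide exactly with missing x")
  if (any((panel$r_y == 0) != is.na(panel$y))) stop("r_y = 0 must coincide exactly with missing y")
  if (any(panel$a[panel$t == 0] != 0)) stop("treatment at t = 0 must be structurally zero")
  ## drop-out absorbing
  bad <- tapply(seq_len(nrow(panel)), panel$id, function(i) {
    i <- i[order(panel$t[i])]
    cc <- panel$c[i]
    if (any(cc == 1)) {
      from <- which(cc == 1)[1]
      any(cc[from:length(cc)] != 1) ||
        any(panel$r_x[i][from:length(cc)] != 0) ||
        any(panel$r_y[i][from:length(cc)] != 0)
    } else FALSE
  })
  if (any(unlist(bad))) stop("drop-out must be absorbing: c = 1 implies all later cells unobserved")
  if (complete && (any(panel$r_x == 0) || any(panel$r_y == 0)))
    stop("panel has missing cells but a complete panel was required")
  invisible(panel)
}

## reshape a (sorted) panel into per-person matrices; assumes validity
panel_mats <- function(panel) {
  panel <- panel[order(panel$id, panel$t), ]
  T_ <- max(panel$t) + 1L
  n <- nrow(panel) / T_
  byrow <- function(col) matrix(panel[[col]], nrow = n, ncol = T_, byrow = TRUE)
  list(
    ids = panel$id[panel$t == 0],
    n = n, T = T_,
    b_bin = panel$b_bin[panel$t == 0],
    b_cont = panel$b_cont[panel$t == 0],
    X = byrow("x"), A = byrow("a"), Y = byrow("y"),
    RX = byrow("r_x"), RY = byrow("r_y"), C = byrow("c")
  )
}

## inverse of panel_mats
mats_panel <- function(m) {
  T_ <- m$T
  data.frame(
    id = rep(m$ids, each = T_),
    t = rep(seq_len(T_) - 1L, m$n),
    b_bin = rep(m$b_bin, each = T_),
    b_cont = rep(m$b_cont, each = T_),
    x = as.vector(t(m$X)),
    a = as.vector(t(m$A)),
    y = as.vector(t(m$Y)),
    r_x = as.vector(t(m$RX)),
    r_y = as.vector(t(m$RY)),
    c = as.vector(t(m$C))
  )
}

#' Write / read a panel as long-format CSV
#'
#' Missing cells are written as empty strings; observation indicators are
#' stored explicitly so files are self-describing and the round trip is
#' lossless.
#'
#' @param panel a panel data frame
#' @param path file path
#' @export
write_panel_csv <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(panel[, c("id", "t", "b_bin", "b_cont", "x", "a", "y", "r_x", "r_y", "c")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "",
                        colClasses = c(id = "integer", t = "integer",
                                       b_bin = "integer", b_cont = "numeric",
                                       x = "numeric", a = "numeric", y = "numeric",
                                       r_x = "integer", r_y = "integer", c = "integer"))
  validate_panel(df)
}

#' Deterministic small test panels
#'
#' Builds 20-person, 5-visit panels exhibiting the canonical longitudinal
#' missing-data patterns: intermittent single-variable missingness,
#' intermittent missingness in both outcome and confounder, monotone
#' drop-out, a mixture of all three, or fully complete data.
#'
#' @param kind one of `"complete"`, `"table1_patient1"` (X and Y missing
#'   alternately at t = 1..4), `"table1_patient2"` (both missing at
#'   t = 1, 2, observed again afterwards), `"dropout"` (absorbing
#'   missingness from t = 2), `"mixed"` (five ids of each of the above).
#' @param seed RNG seed for the underlying complete data
#' @return a panel data frame
#' @export
make_fixture <- function(kind = c("complete", "table1_patient1", "table1_patient2",
                                  "dropout", "mixed"),
                         seed = 1) {
  kind <- match.arg(kind)
  co <- dgp_coefficients()
  sp <- scenario_spec(n = 20, pattern = "monotone", level = "low")
  panel <- generate_complete_panel(sp, co, seed = seed)
  m <- panel_mats(panel)

  blank <- function(m, ids, tt, what) {
    rows <- m$ids %in% ids
    if (what %in% c("x", "both")) { m$RX[rows, tt + 1L] <- 0L; m$X[rows, tt + 1L] <- NA_real_ }
    if (what %in% c("y", "both")) { m$RY[rows, tt + 1L] <- 0L; m$Y[rows, tt + 1L] <- NA_real_ }
    m
  }
  apply_kind <- function(m, ids, kind) {
    switch(kind,
      complete = m,
      table1_patient1 = {
        m <- blank(m, ids, c(1L, 3L), "y")
        blank(m, ids, c(2L, 4L), "x")
      },
      table1_patient2 = blank(m, ids, c(1L, 2L), "both"),
      dropout = {
        m <- blank(m, ids, 2:4, "both")
        m$C[m$ids %in% ids, 3:5] <- 1L
        m
      })
  }
  if (kind == "mixed") {
    m <- apply_kind(m, m$ids[1:5], "table1_patient1")
    m <- apply_kind(m, m$ids[6:10], "table1_patient2")
    m <- apply_kind(m, m$ids[11:15], "dropout")
  } else {
    m <- apply_kind(m, m$ids, kind)
  }
  validate_panel(mats_panel(m))
}
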
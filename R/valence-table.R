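# Valence-state parameter table: the empirical input of the whole model.
# Every PPP parameter (U_r, gamma_rr, gamma_rs, beta_rs) derives from the
# per-type ionization potential IP_v and electron affinity EA_v, plus the
# single global constant C = 0.545 in the resonance integral.

#' Load a valence-state parameter table
#'
#' Reads a CSV of valence-state ionization potentials and electron
#' affinities (one row per pi-center type).  The Slater 2p exponent of
#' each type is derived from the mean of IP_v and EA_v,
#' \eqn{\zeta = n \sqrt{(IP_v + EA_v)/E_h}} with \eqn{n = 2} and
#' \eqn{E_h} the Hartree energy in eV, so the table is fully determined
#' by the two experimental columns.
#'
#' @param path CSV file with columns `key`, `element`, `sigma_neighbors`,
#'   `n_pi`, `ip_ev`, `ea_ev`.  Defaults to the table shipped with the
#'   package.
#' @return A data frame of class `ppp_valence_table` with an additional
#'   `zeta` column, the Slater 2p exponent in 1/Angstrom used inside the
#'   overlap integrals.
#' @export
#' @examples
#' tab <- valenceStateTable()
#' tab[tab$key == "C.sp2", ]
valenceStateTable <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "valence_states.csv", package = "pppgap")
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("key", "element", "sigma_neighbors", "n_pi", "ip_ev", "ea_ev")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("valence table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(tab$ip_ev <= tab$ea_ev)) {
    stop("valence table invariant violated: IP_v must exceed EA_v", call. = FALSE)
  }
  if (any(tab$ip_ev <= 0)) stop("valence table requires positive IP_v", call. = FALSE)
  # 2p orbital exponent from the mean valence-state orbital energy
  tab$zeta <- 2 * sqrt((tab$ip_ev + tab$ea_ev) / pppConstants$hartree_ev)
  class(tab) <- c("ppp_valence_table", "data.frame")
  tab
}

.default_table_cache <- new.env(parent = emptyenv())

#' Default valence-state table (cached)
#' @return The packaged `ppp_valence_table`.
#' @export
defaultValenceTable <- function() {
  if (is.null(.default_table_cache$tab)) {
    .default_table_cache$tab <- valenceStateTable()
  }
  .default_table_cache$tab
}

.valence_entry <- function(key, table = defaultValenceTable()) {
  i <- match(key, table$key)
  if (anyNA(i)) {
    stop("unsupported pi-center type(s): ",
         paste(unique(key[is.na(i)]), collapse = ", "),
         "; parameterized types: ", paste(table$key, collapse = ", "),
         call. = FALSE)
  }
  table[i, , drop = FALSE]
}
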
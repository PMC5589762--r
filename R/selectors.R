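#' @include AllClasses.R AllGenerics.R
NULL

#' Build an atom selector
#'
#' Selectors express subsets such as "backbone atoms of chain A, residues
#' 26-113". Resolution is deterministic and preserves file order.
#'
#' @param chains character vector of chain ids to keep (default: all).
#' @param resnoMin,resnoMax inclusive residue-number range.
#' @param atomNames character vector of atom names to keep (default: all).
#'   The convenience value `"backbone"` expands to `N`, `CA`, `C`, `O`.
#' @param heavyOnly keep only non-hydrogen atoms.
#' @return An [AtomSelector-class].
#' @examples
#' sel <- atomSelector(chains = "C", atomNames = "backbone")
#' @export
atomSelector <- function(chains = character(0), resnoMin = -Inf,
                         resnoMax = Inf, atomNames = character(0),
                         heavyOnly = FALSE) {
  if (length(atomNames) == 1L && atomNames == "backbone")
    atomNames <- c("N", "CA", "C", "O")
  new("AtomSelector", chains = as.character(chains),
      resnoMin = as.numeric(resnoMin), resnoMax = as.numeric(resnoMax),
      atomNames = as.character(atomNames), heavyOnly = heavyOnly)
}

#' Resolve a selector to atom indices
#'
#' @param structure a [Structure-class].
#' @param selector an [AtomSelector-class].
#' @return Integer vector of atom indices, in file order.
#' @export
resolveSelection <- function(structure, selector) {
  a <- atomData(structure)
  keep <- rep(TRUE, nrow(a))
  if (length(selector@chains) > 0L) keep <- keep & a$chain %in% selector@chains
  keep <- keep & a$resno >= selector@resnoMin & a$resno <= selector@resnoMax
  if (length(selector@atomNames) > 0L)
    keep <- keep & a$elety %in% selector@atomNames
  if (selector@heavyOnly) keep <- keep & !is_hydrogen(a$elesy)
  which(keep)
}
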
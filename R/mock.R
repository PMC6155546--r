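## Mock-community specifications.
##
## The bundled presets MC1-MC4 encode the published mock compositions: a
## two-phylum split (Firmicutes/Proteobacteria) crossed with within-phylum
## species percentages (MC1-MC3, 15 species / one strain each) or with
## per-strain percentages over 14 strains of 5 species (MC4).

# strain-level composition table shared by the presets ------------------------

mock_strain_table <- function() {
  # taxonomy: class;order;family per species (domain=Bacteria fixed)
  sp <- function(species, genus, family, ord, class, phylum)
    c(domain = "Bacteria", phylum = phylum, class = class, order = ord,
      family = family, genus = genus, species = species)
  tax <- list(
    "Lactobacillus algidus"        = sp("Lactobacillus algidus", "Lactobacillus", "Lactobacillaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Lactobacillus sakei"          = sp("Lactobacillus sakei", "Lactobacillus", "Lactobacillaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Lactococcus piscium"          = sp("Lactococcus piscium", "Lactococcus", "Streptococcaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Brochothrix thermosphacta"    = sp("Brochothrix thermosphacta", "Brochothrix", "Listeriaceae", "Bacillales", "Bacilli", "Firmicutes"),
    "Carnobacterium divergens"     = sp("Carnobacterium divergens", "Carnobacterium", "Carnobacteriaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Carnobacterium maltaromaticum"= sp("Carnobacterium maltaromaticum", "Carnobacterium", "Carnobacteriaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Leuconostoc gelidum"          = sp("Leuconostoc gelidum", "Leuconostoc", "Leuconostocaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Weissella viridescens"        = sp("Weissella viridescens", "Weissella", "Leuconostocaceae", "Lactobacillales", "Bacilli", "Firmicutes"),
    "Pseudomonas fragi"            = sp("Pseudomonas fragi", "Pseudomonas", "Pseudomonadaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria"),
    "Pseudomonas lundensis"        = sp("Pseudomonas lundensis", "Pseudomonas", "Pseudomonadaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria"),
    "Acinetobacter guillouiae"     = sp("Acinetobacter guillouiae", "Acinetobacter", "Moraxellaceae", "Pseudomonadales", "Gammaproteobacteria", "Proteobacteria"),
    "Photobacterium phosphoreum"   = sp("Photobacterium phosphoreum", "Photobacterium", "Vibrionaceae", "Vibrionales", "Gammaproteobacteria", "Proteobacteria"),
    "Serratia proteamaculans"      = sp("Serratia proteamaculans", "Serratia", "Yersiniaceae", "Enterobacterales", "Gammaproteobacteria", "Proteobacteria"),
    "Hafnia alvei"                 = sp("Hafnia alvei", "Hafnia", "Hafniaceae", "Enterobacterales", "Gammaproteobacteria", "Proteobacteria"),
    "Morganella psychrotolerans"   = sp("Morganella psychrotolerans", "Morganella", "Morganellaceae", "Enterobacterales", "Gammaproteobacteria", "Proteobacteria")
  )
  list(tax = tax)
}

# fraction of a species' amplifiable template that is parE rather than gyrB;
# zero outside Firmicutes (the primers only co-amplify parE there).
default_pare_fractions <- function() {
  c("Lactobacillus algidus"         = 0.80,
    "Lactobacillus sakei"           = 0.30,
    "Lactococcus piscium"           = 0.40,
    "Brochothrix thermosphacta"     = 0.80,
    "Carnobacterium divergens"      = 0.85,
    "Carnobacterium maltaromaticum" = 0.85,
    "Leuconostoc gelidum"           = 0.75,
    "Weissella viridescens"         = 0.75,
    "Pseudomonas fragi"             = 0,
    "Pseudomonas lundensis"         = 0,
    "Acinetobacter guillouiae"      = 0,
    "Photobacterium phosphoreum"    = 0,
    "Serratia proteamaculans"       = 0,
    "Hafnia alvei"                  = 0,
    "Morganella psychrotolerans"    = 0)
}

# within-phylum species percentages for the 15-species presets (MC1-MC3)
interspecies_members <- function() {
  data.frame(
    strain_id = c("CMTALT10", "23K", "CMTALT02", "160x8", "MFPA43A14-05",
                  "DSM20342", "MFPA44A14-01", "MFPC16A28-05",
                  "ATCC4973", "MFPA15A12-05", "MFPA43A14-04", "CIP105612",
                  "MFPA44A14-05", "CIP57.31", "MFPA43A14-03"),
    species = c("Lactobacillus algidus", "Lactobacillus sakei",
                "Lactococcus piscium", "Brochothrix thermosphacta",
                "Carnobacterium divergens", "Carnobacterium maltaromaticum",
                "Leuconostoc gelidum", "Weissella viridescens",
                "Pseudomonas fragi", "Pseudomonas lundensis",
                "Acinetobacter guillouiae", "Photobacterium phosphoreum",
                "Serratia proteamaculans", "Hafnia alvei",
                "Morganella psychrotolerans"),
    within_phylum = c(0.05, 0.35, 0.10, 0.05, 0.10, 0.10, 0.05, 0.20,
                      0.20, 0.15, 0.05, 0.25, 0.10, 0.05, 0.20),
    stringsAsFactors = FALSE)
}

# per-strain within-phylum percentages for the intra-species preset (MC4)
intraspecies_members <- function() {
  data.frame(
    strain_id = c("23K", "DSM20017", "DSM15831",
                  "160x8", "cH814", "ATCC11509",
                  "MFPA44A14-01", "DSM5578",
                  "MFPA15A12-05", "MFPB42A12-09", "PCAi-D2.2",
                  "MFPA44A14-05", "1C2F", "CIP103236"),
    species = c(rep("Lactobacillus sakei", 3),
                rep("Brochothrix thermosphacta", 3),
                rep("Leuconostoc gelidum", 2),
                rep("Pseudomonas lundensis", 3),
                rep("Serratia proteamaculans", 3)),
    within_phylum = c(0.20, 0.20, 0.20, 0.10, 0.05, 0.05, 0.15, 0.05,
                      0.20, 0.10, 0.10, 0.20, 0.20, 0.20),
    stringsAsFactors = FALSE)
}

#' Construct a mock-community specification
#'
#' @param name community name.
#' @param members `data.frame(strain_id, species, proportion)` with taxonomy
#'   resolvable through the bundled species table; proportions must sum to 1.
#' @param pare_fraction named numeric, species -> fraction of that species'
#'   reads originating from parE (must be 0 for non-Firmicutes).
#' @param depth reads per sample.
#' @param error_rate per-base substitution rate.
#' @param chimera_rate fraction of reads replaced by two-parent chimeras.
#' @param total_cfu total community load in CFU.g^-1 (drives the simulated
#'   qPCR).
#' @param seed integer seed recorded with the spec.
#' @return object of class `mock_spec`.
#' @export
mock_spec <- function(name, members, pare_fraction = default_pare_fractions(),
                      depth = 50000L, error_rate = 1e-3,
                      chimera_rate = 0.012, total_cfu = 1e8, seed = 1L) {
  stopifnot(is.data.frame(members),
            all(c("strain_id", "species", "proportion") %in% names(members)))
  if (abs(sum(members$proportion) - 1) > 1e-9)
    stop("member proportions must sum to 1", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  tab <- mock_strain_table()$tax
  unknown <- setdiff(members$species, names(tab))
  if (length(unknown))
    stop("species without bundled taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pf <- pare_fraction[members$species]
  if (anyNA(pf))
    stop("pare_fraction missing for: ",
         paste(unique(members$species[is.na(pf)]), collapse = ", "),
         call. = FALSE)
  phyla <- vapply(members$species, function(s) tab[[s]][["phylum"]], character(1L))
  if (any(pf > 0 & phyla != "Firmicutes"))
    stop("pare_fraction must be 0 for non-Firmicutes species", call. = FALSE)
  if (any(pf < 0 | pf > 1)) stop("pare_fraction must lie in [0,1]", call. = FALSE)
  structure(list(name = name, members = members,
                 pare_fraction = pare_fraction, depth = as.integer(depth),
                 error_rate = error_rate, chimera_rate = chimera_rate,
                 total_cfu = total_cfu, seed = as.integer(seed)),
            class = "mock_spec")
}

#' Bundled mock-community presets
#'
#' MC1-MC3 mix the same 15 species (one strain each) at phylum splits of
#' 99/1, 50/50 and 1/99 (Firmicutes/Proteobacteria); MC4 mixes 14 strains of
#' 5 species at 65/35 with known per-strain percentages.
#'
#' @param name `"MC1"`, `"MC2"`, `"MC3"` or `"MC4"`.
#' @param ... overrides passed on to [mock_spec()] (e.g. `depth`, `seed`).
#' @return a [mock_spec()].
#' @export
mock_preset <- function(name = c("MC1", "MC2", "MC3", "MC4"), ...) {
  name <- match.arg(name)
  firm_frac <- switch(name, MC1 = 0.99, MC2 = 0.50, MC3 = 0.01, MC4 = 0.65)
  mem <- if (name == "MC4") intraspecies_members() else interspecies_members()
  tab <- mock_strain_table()$tax
  phyla <- vapply(mem$species, function(s) tab[[s]][["phylum"]], character(1L))
  mem$proportion <- mem$within_phylum *
    ifelse(phyla == "Firmicutes", firm_frac, 1 - firm_frac)
  mem$within_phylum <- NULL
  mock_spec(name = name, members = mem, ...)
}

#' @export
print.mock_spec <- function(x, ...) {
  tab <- mock_strain_table()$tax
  phyla <- vapply(x$members$species, function(s) tab[[s]][["phylum"]], character(1L))
  cat(sprintf("mock_spec '%s': %d strains, %d species (Firmicutes %.1f%%), depth %d\n",
              x$name, nrow(x$members), length(unique(x$members$species)),
              100 * sum(x$members$proportion[phyla == "Firmicutes"]), x$depth))
  invisible(x)
}

# taxonomy vector (7 ranks + strain) for a member strain
member_taxonomy <- function(species, strain_id) {
  tab <- mock_strain_table()$tax
  c(tab[[species]], strain = strain_id)
}
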
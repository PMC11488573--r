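# Small deterministic community fixture used across pipeline tests.
# Fixers: Vicia_a, Vicia_b, Trifolium_c (genus-level trait); non-fixers:
# Quercus_d, Poa_e, Carex_f.
fixture_tree <- function() {
  parse_newick(paste0(
    "(((Vicia_a:20,Vicia_b:20):30,Trifolium_c:50):50,",
    "((Quercus_d:40,Poa_e:40):30,Carex_f:70):30);"))
}

fixture_traits <- function() {
  data.frame(
    species = c("Vicia_a", "Vicia_b", "Trifolium_c",
                "Quercus_d", "Poa_e", "Carex_f"),
    genus = c("Vicia", "Vicia", "Trifolium", "Quercus", "Poa", "Carex"),
    family = c("Fabaceae", "Fabaceae", "Fabaceae",
               "Fagaceae", "Poaceae", "Cyperaceae"),
    is_fixer = c(1, 1, 1, 0, 0, 0))
}

fixture_pairs <- function() {
  make_survey_pairs(fixture_community())
}

# Three plots across two sites:
#  p1: fixers {Vicia_a, Vicia_b} -> {Vicia_b, Trifolium_c}
#  p2: fixers {Trifolium_c}      -> {} (all fixers lost)
#  p3: no fixers in either survey (filtered everywhere)
fixture_community <- function() {
  long <- function(plot, site, role, year, species)
    data.frame(plot = plot, site = site, survey_role = role, year = year,
               species = species)
  rbind(
    long("p1", "s1", "baseline", 1970,
         c("Vicia_a", "Vicia_b", "Quercus_d", "Poa_e")),
    long("p1", "s1", "resurvey", 2010,
         c("Vicia_b", "Trifolium_c", "Quercus_d")),
    long("p2", "s1", "baseline", 1970, c("Trifolium_c", "Poa_e", "Carex_f")),
    long("p2", "s1", "resurvey", 2010, c("Poa_e", "Carex_f", "Quercus_d")),
    long("p3", "s2", "baseline", 1975, c("Quercus_d", "Poa_e")),
    long("p3", "s2", "resurvey", 2005, c("Poa_e", "Carex_f")))
}

fixture_env <- function() {
  rbind(
    data.frame(site = "s1", year = 1960:2010, n_dep = 0.8, temp = 8,
               precip = 800, pet = 700),
    data.frame(site = "s2", year = 1960:2010, n_dep = 0.4, temp = 9,
               precip = 900, pet = 650))
}
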
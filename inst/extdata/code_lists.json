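{
  "version": "1.0",
  "notes": "Default code lists for outcome labeling. Stand-ins for site-specific lists: standard uropathogens, UTI-relevant antibiotics, nonspecific diagnoses attributable to UTI, and alternative infectious diagnoses that would explain an antibiotic prescription. All lists are overridable; matching is exact on case-folded, trimmed labels.",
  "pathogenic_organisms": [
    "Escherichia coli",
    "Klebsiella pneumoniae",
    "Klebsiella oxytoca",
    "Proteus mirabilis",
    "Enterobacter cloacae",
    "Citrobacter freundii",
    "Citrobacter koseri",
    "Pseudomonas aeruginosa",
    "Enterococcus faecalis",
    "Enterococcus faecium",
    "Staphylococcus saprophyticus",
    "Serratia marcescens",
    "Streptococcus agalactiae"
  ],
  "uti_explicit_dx": [
    "urinary tract infection",
    "uti",
    "acute cystitis",
    "cystitis",
    "acute pyelonephritis",
    "pyelonephritis",
    "urinary tract infection, site not specified",
    "recurrent urinary tract infection"
  ],
  "uti_relevant_antibiotics": [
    "nitrofurantoin",
    "trimethoprim-sulfamethoxazole",
    "cephalexin",
    "ciprofloxacin",
    "levofloxacin",
    "fosfomycin",
    "amoxicillin-clavulanate",
    "ceftriaxone"
  ],
  "nonspecific_uti_attributable_dx": [
    "dysuria",
    "urinary frequency",
    "urinary urgency",
    "hematuria",
    "abdominal pain",
    "flank pain",
    "altered mental status",
    "fever unspecified"
  ],
  "alternative_infectious_dx": [
    "pneumonia",
    "cellulitis",
    "otitis media",
    "pharyngitis",
    "sexually transmitted infection",
    "intra-abdominal infection",
    "skin abscess",
    "sinusitis"
  ]
}
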
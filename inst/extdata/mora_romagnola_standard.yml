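# Redefined Mora Romagnola Herd Book standard: phenotype descriptors plus
# the allowed genotypes at the MC1R (Extension) and NR6A1 loci.
name: Mora Romagnola
allowed_genotypes:
  MC1R: ["e/e", "E+/e", "E+/E+"]
  NR6A1: ["T/T"]
phenotype_rules:
  boar:
    coat_colour: [black_and_tan]
    ears: [bent_forward_parallel]
    linea_sparta: [present]
  sow:
    coat_colour: [black_and_tan]
    ears: [bent_forward_parallel]
    linea_sparta: [present]
  young:
    coat_colour: [black_and_tan, red, other]
    ears: [bent_forward_parallel, half_hanging, raised, other]
    linea_sparta: [present, absent]
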
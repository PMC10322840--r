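# RAF/KSR sequence accessions (one id per line, tab-separated label).
# These public records are NOT bundled: the package's tested core uses only
# synthetic stand-ins. The optional helper inst/scripts/fetch-accessions.sh
# can download them for real-data analyses.
P15056	Homo_sapiens_BRAF
P10398	Homo_sapiens_ARAF
P04049	Homo_sapiens_CRAF
Q8IVT5	Homo_sapiens_KSR1
Q6VAB6	Homo_sapiens_KSR2
MW803455	Paracentrotus_lividus_RAF
MW803454	Paracentrotus_lividus_KSR1
MW691984	Paracentrotus_lividus_KSR3
XP_781094.4	Strongylocentrotus_purpuratus_RAF
XP_030847715.1	Strongylocentrotus_purpuratus_KSR1
XP_780355.4	Strongylocentrotus_purpuratus_KSR3
XM_006825955.1	Saccoglossus_kowalevskii_KSR3
XP_006821654	Saccoglossus_kowalevskii_BRAF
XP_006821895.1	Saccoglossus_kowalevskii_KSR1
XP_032227537.1	Nematostella_vectensis_KSR3
XP_032220394.1	Nematostella_vectensis_KSR1
EDO47089.1	Nematostella_vectensis_RAF
XP_029213160.1	Acropora_millepora_KSR3
XP_002110813.1	Trichoplax_adhaerens_KSR3
XP_014664712.1	Priapulus_caudatus_KSR3
XP_022249006.1	Limulus_polyphemus_KSR3
XP_037511753.1	Rhipicephalus_sanguineus_KSR3
XP_034325584.1	Crassostrea_gigas_KSR3
XP_009044189.1	Lottia_gigantea_KSR3
XP_013397833.1	Lingula_anatina_KSR3
ELT92102.1	Capitella_teleta_KSR3
PMI_015081.1	Patiria_miniata_KSR3
XP_033117077.1	Anneissia_japonica_KSR3
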
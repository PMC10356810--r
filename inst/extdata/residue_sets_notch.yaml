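# Ligand-binding interface and calcium-binding residues of the EGF11-12
# repeats of human NOTCH1 and NOTCH2 (protein residue numbering).
notch1_interface:
  provenance: >-
    Ligand-binding interface residues of NOTCH1 EGF11-12 (union of the
    JAG1 and DLL4 interfaces mapped from rat NOTCH1).
  residues: [413, 415, 418, 420, 421, 422, 423, 424, 425, 435, 436, 444,
             447, 448, 450, 451, 452, 454, 466, 467, 468, 469, 470, 471,
             475, 477, 478, 479, 480]
notch2_interface:
  provenance: >-
    Ligand-binding interface residues of NOTCH2 EGF11-12, by conservation
    with the rat NOTCH1 ligand interface.
  residues: [418, 421, 424, 425, 426, 428, 429, 439, 440, 452, 454, 456,
             470, 472, 473, 481]
notch1_calcium:
  provenance: >-
    Calcium-binding residues of NOTCH1 EGF11-12 (metal-site annotation of
    structure 2VJ3).
  residues: [412, 413, 415, 431, 432, 435, 452, 453, 455, 469, 470]
notch2_calcium:
  provenance: >-
    Calcium-binding residues of NOTCH2 EGF11-12 (metal-site annotation of
    structure 5MWB).
  residues: [415, 416, 418, 435, 436, 439, 456, 457, 459, 473, 474]
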
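>synthetic_hpylori synthetic fragment carrying KLVFF
MTNARDKLVFFGQSTPLEH
>synthetic_borrelia synthetic fragment carrying VGSNK
GSLEQVGSNKTTRADW
>synthetic_phage synthetic fragment carrying VGGVV
AKPHVGGVVLDNQERS
>synthetic_decoy synthetic fragment with no embedded motif
PQWTNHRDCEMYSTW
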
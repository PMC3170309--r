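#technical_fail syntax.invalid_qname
#technical_fail syntax.flag_range
#technical_fail syntax.pos_range
#technical_fail syntax.unknown_reference
#technical_fail syntax.seq_qual_mismatch
#technical_fail syntax.zero_length_read
#technical_fail syntax.invalid_cigar
#technical_fail functional.cigar_on_unmapped
#technical_fail functional.mapq_on_unmapped
#technical_fail functional.unknown_read_group
#technical_fail functional.maps_beyond_reference
#technical_fail functional.adjacent_indel
#technical_fail functional.proper_pair_without_pairing
#technical_fail functional.invalid_nm
pattern	bound_type	bound	action
FILE_*_MAPPING_RATIO	min	0.50	FAIL
FILE_*_MAPQ_MEAN	min	20.00	WARN
GROUP_*_MAPQ_MEAN	min	20.00	WARN
FILE_*_ANOMALOUS_FRACTION	max	0.05	WARN
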
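metaterm	target_id	target_kind	excluded
anatomy	D001	descriptor	0
anatomy	D005	descriptor	0
toxicology	D006	descriptor	0
toxicology	D008	descriptor	0
psychiatry	D008	descriptor	0
psychiatry	D009	descriptor	0
psychiatry	D010	descriptor	0
psychiatry	D011	descriptor	0
statistics	D012	descriptor	1
therapeutics	Q001	qualifier	0
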
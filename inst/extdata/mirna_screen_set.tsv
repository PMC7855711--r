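mirna_id
miR-30a-5p
miR-205-3p
miR-302c-3p
miR-330-5p
miR511-5p
miR-544a
miR-1231
miR-3619-5p
miR-4464
miR-4660
miR-4743-3p
miR-7978
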
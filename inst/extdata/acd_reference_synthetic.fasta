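>cyanophage_template synthetic ACD reference row
NDPPYNIVWSCIKQVVHEWHRFVIIHQVNFLCLAGFLVWFINHIQRLFQKFRFVMFKQWF
RCEEHSKHMMWRTILFQMMHCFESQCCMLNLV
>bacterial_class_A_template synthetic ACD reference row
EIHECRMQWMWIKQVYISWHEVVVILQTNSLTLAGFRHQQINIIHRDQFTQWVVMFKQIF
RCEEFSKHMMWRVIWMCCNHFFESQCYMYILV
>class_B_plant_template synthetic ACD reference row
LKRRFLYFWKHIKQVSVFWHRHVCINQNNYLNVPGKYCLDINVICRMTYNCLFVMFKQFF
RCEEDSKHMMWRWIFKDLNHMTESQCMMDDLH
>cyanobacterial_template synthetic ACD reference row
NDLFHICTWEDIKQVYMEWHLEVSILQKNHLWVPGKSEHKINQIWRTCDDTDMVMFKQFF
RCEEKSKHMMWRMIMFKKVHKCESQCTMMRLQ
>cyanophage_variant synthetic ACD reference row
EDPPYNIVWWIIKQVVHEWHRFVIIHQVRFLCLAGFLVWFINSIQRLFSKFRFVMFKQWF
RCEEHSKHMMWRTILGQMMHCFESQCCMLNLD
>bacterial_class_A_variant synthetic ACD reference row
EIHECRMQWALIKQVYISWHCVVVILQTNSLMLAGFRHQQINIIHRDQFTIWVVMFKQIF
RCEEFSKHMMWRVIWISCNHFFEDQCYMYILV
>class_B_plant_variant synthetic ACD reference row
LDRRFLYFWWGIKQVSVFWHRHVCINQNNYLGVPGKYCLDINVICRMTVNCLVVMFKQFF
RCEEDSKHMMWRWIFKDLNHMTESQCMMDDCD
>cyanobacterial_variant synthetic ACD reference row
NILFHICTWEPIKQVYMQWLLEVSILQKLHLWVPGKSEHKINQIWRTCDDTVAEMFKQFF
RCEEKSKHMMWRMIMFKKVHKCESQCTMMRLQ
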
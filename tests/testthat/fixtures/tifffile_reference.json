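{"py_le16": "49492a00080000000e000001040001000000090000000101040001000000060000000201030001000000100000000301030001000000010000000601030001000000010000000e01020015000000b600000011010400010000000001000015010300010000000100000016010400010000000600000017010400010000006c0000001a01050001000000da0000001b01050001000000e2000000280103000100000001000000310102000c000000ea000000440200007b227368617065223a205b332c20362c20395d7d00000000000000000000000000000000010000000100000001000000010000007469666666696c652e707900000000000000000000008b4ae5f1a94106a0956a26afbccdafe562f90a945f5693c642276ad5ab2da7394551370e99b2d74c3427fa48d732a1df70aca1e926115901dd06f27f8f063cd25e19a621f9bd0ccc21397c1ec795ca7748dc03d17a88934d85527357a2e64647f03e2fb81f223f4192c58efd5185f0711ef7677a1f132a818d882195a100b28d6b236b82481bd9fe630dc3ce3be4ebcab72f45b35223479f6e794d57037e2cfde9e15a7789781e3721a557d8e5a703296dcb81db3f65cf9c1bdc5d1d8fc83f0b0bb4db71be572209851d3d24f4c0cf83fe4363f82f4759778955f6ced681cbea7179ced2c8f814a13472ff70ce369d8385452a44f318337f08cd1e614f235d3f83bc45fee9ee0403a79be118544441317c9311f85e0429b19f7ec0e156f65a3322e791b880ee995e3f0d307d2fbaf400693a179e0d027ed4e58be7a9ebc28a271d43a7880c0000010400010000000900000001010400010000000600000002010300010000001000000003010300010000000100000006010300010000000100000011010400010000006c01000015010300010000000100000016010400010000000600000017010400010000006c0000001a01050001000000da0200001b01050001000000e2020000280103000100000001000000ea020000010000000100000001000000010000000c000001040001000000090000000101040001000000060000000201030001000000100000000301030001000000010000000601030001000000010000001101040001000000d801000015010300010000000100000016010400010000000600000017010400010000006c0000001a01050001000000da0200001b01050001000000e20200002801030001000000010000000000000001000000010000000100000001000000", "py_be16": "4d4d002a00000008000e010000040000000100000009010100040000000100000006010200030000000100100000010300030000000100010000010600030000000100010000010e000200000015000000b601110004000000010000010001150003000000010001000001160004000000010000000601170004000000010000006c011a000500000001000000da011b000500000001000000e2012800030000000100010000013100020000000c000000ea000002447b227368617065223a205b332c20362c20395d7d00000000000000000000000000000000000000010000000100000001000000017469666666696c652e707900000000000000000000004a8bf1e541a9a0066a95af26cdbce5aff962940a565fc6932742d56a2dab39a751450e37b2994cd7273448fa32d7dfa1ac70e9a11126015906dd7ff2068fd23c195e21a6bdf9cc0c39211e7c95c777cadc48d103887a4d9352855773e6a247463ef0b82f221f413fc592fd8e855171f0f71e7a67131f812a888d952100a18db2236b826b1b48fed90d63cec3e43bcaeb2fb7b34523529f47796e574d7e03fd2ce1e9775a7889371ea521d857a7e52903cb6ddb81653f9ccfdc1b1d5dc88f0b3fb40b71db57be09221d85243dc0f483cf43fef863472f77595589cef681d6eacb7971d2cef8c8a114723470ff36ce839d4585442a18f37f33cd08611e234f3f5dbc83fe45eee903049ba718e144543141937cf811045eb1297e9fe1c0f656335ae722b891ee805e990d3f7d30ba2f00f43a699e17020dd47e8be5a9e7c2eb278a431d88a7000c01000004000000010000000901010004000000010000000601020003000000010010000001030003000000010001000001060003000000010001000001110004000000010000016c01150003000000010001000001160004000000010000000601170004000000010000006c011a000500000001000002da011b000500000001000002e2012800030000000100010000000002ea00000001000000010000000100000001000c0100000400000001000000090101000400000001000000060102000300000001001000000103000300000001000100000106000300000001000100000111000400000001000001d801150003000000010001000001160004000000010000000601170004000000010000006c011a000500000001000002da011b000500000001000002e20128000300000001000100000000000000000001000000010000000100000001", "py_8": "49492a00080000000e000001040001000000050000000101040001000000040000000201030001000000080000000301030001000000010000000601030001000000010000000e01020015000000b60000001101040001000000000100001501030001000000010000001601040001000000040000001701040001000000140000001a01050001000000da0000001b01050001000000e2000000280103000100000001000000310102000c000000ea000000280100007b227368617065223a205b322c20342c20355d7d00000000000000000000000000000000010000000100000001000000010000007469666666696c652e7079000000000000000000000055638144eb6603f7b2725de11fe6ac2f88a68182869793f0aad6ded8116e3ab51681c4a374fec70a0c000001040001000000050000000101040001000000040000000201030001000000080000000301030001000000010000000601030001000000010000001101040001000000140100001501030001000000010000001601040001000000040000001701040001000000140000001a01050001000000be0100001b01050001000000c60100002801030001000000010000000000000001000000010000000100000001000000", "px16": [[[19083, 61925, 16809, 40966, 27285, 44838, 52668, 58799, 63842], [37898, 22111, 50835, 10050, 54634, 11691, 14759, 20805, 3639], [45721, 19671, 10036, 18682, 13015, 57249, 44144, 59809, 4390], [345, 1757, 32754, 1679, 53820, 6494, 8614, 48633, 52236], [14625, 7804, 38343, 30666, 56392, 53507, 34938, 19859, 21125], [22387, 59042, 18246, 16112, 47151, 8735, 16703, 50578, 64910]], [[34129, 29168, 63262, 31335, 4895, 33066, 34957, 38177, 161], [36274, 9067, 33387, 6984, 65241, 3427, 52931, 58427, 51947], [12215, 45893, 9042, 40775, 31086, 22349, 32259, 64812, 57833], [30554, 30857, 14110, 42273, 55383, 42981, 10499, 52077, 56193], [25919, 40143, 56347, 7517, 51343, 2879, 46091, 29147, 22462], [2338, 7557, 9277, 49396, 33743, 17406, 63587, 18223, 30553]], [[21897, 52982, 33238, 60107, 31089, 53966, 63688, 41236, 29236], [28927, 14030, 33693, 17797, 17450, 6387, 32563, 52488, 24862], [9039, 16221, 48259, 65093, 61161, 772, 39847, 6369, 17492], [12609, 37756, 63505, 1118, 45353, 32415, 57792, 63062, 13146], [59170, 47249, 61056, 24217, 3391, 32048, 47663, 244, 14953], [40471, 525, 54398, 35813, 43495, 49899, 10122, 17181, 34983]]], "px8": [[[85, 99, 129, 68, 235], [102, 3, 247, 178, 114], [93, 225, 31, 230, 172], [47, 136, 166, 129, 130]], [[134, 151, 147, 240, 170], [214, 222, 216, 17, 110], [58, 181, 22, 129, 196], [163, 116, 254, 199, 10]]]}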